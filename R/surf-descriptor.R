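# Haar wavelet responses at integer centres (r = row, c = col), window side w
# (even). dx is right-half minus left-half, dy bottom-half minus top-half,
# both normalised by half the window area so responses are mean-gradient-like.
haarX <- function(ii, r, c, w) {
  h <- w %/% 2L
  (boxSum(ii, r - h + 1L, c + 1L, w, h) -
   boxSum(ii, r - h + 1L, c - h + 1L, w, h)) / (w * h)
}

haarY <- function(ii, r, c, w) {
  h <- w %/% 2L
  (boxSum(ii, r + 1L, c - h + 1L, h, w) -
   boxSum(ii, r - h + 1L, c - h + 1L, h, w)) / (w * h)
}

# Offsets (in units of scale) of the circular orientation-sampling grid.
orientationGrid <- local({
  g <- expand.grid(i = -6:6, j = -6:6)
  g <- g[g$i^2 + g$j^2 < 36, ]
  g$weight <- exp(-(g$i^2 + g$j^2) / (2 * 2.5^2))
  g
})

#' Assign the dominant orientation of an interest point
#'
#' Haar wavelet responses (window `4*scale`) are sampled on a circular grid
#' of radius `6*scale` around the point, Gaussian-weighted, and scanned with
#' a sliding 60-degree angular window; the window with the largest summed
#' response vector defines the orientation. The angular scan order is fixed,
#' and ties keep the first maximal window, so the result is deterministic.
#'
#' @param ii integral image.
#' @param x,y point coordinates (1-based pixels).
#' @param scale point scale.
#' @return Orientation in radians in `[0, 2*pi)`.
#' @export
assignOrientation <- function(ii, x, y, scale) {
  s <- max(1L, as.integer(round(scale)))
  w <- 4L * s
  r <- as.integer(round(y)) + orientationGrid$j * s
  c <- as.integer(round(x)) + orientationGrid$i * s
  dx <- haarX(ii, r, c, w) * orientationGrid$weight
  dy <- haarY(ii, r, c, w) * orientationGrid$weight
  keep <- dx != 0 | dy != 0
  if (!any(keep)) return(0)
  ang <- atan2(dy[keep], dx[keep]) %% (2 * pi)
  dx <- dx[keep]; dy <- dy[keep]
  best <- -1; orientation <- 0
  for (a1 in seq(0, 2 * pi, by = 0.15)) {
    a2 <- a1 + pi / 3
    inWin <- if (a2 <= 2 * pi) ang >= a1 & ang < a2
             else ang >= a1 | ang < (a2 - 2 * pi)
    if (!any(inWin)) next
    sx <- sum(dx[inWin]); sy <- sum(dy[inWin])
    n2 <- sx * sx + sy * sy
    if (n2 > best) {           # strict: first maximal window wins
      best <- n2
      orientation <- atan2(sy, sx) %% (2 * pi)
    }
  }
  orientation
}

# 12 x 12 descriptor sample offsets in units of scale: window side 20*scale,
# 4 x 4 subregions of side 5*scale, 3 x 3 samples per subregion.
descriptorGrid <- local({
  pos <- -10 + (seq_len(12) - 0.5) * (20 / 12)
  g <- expand.grid(u = pos, v = pos)
  g$subregion <- (findInterval(g$v, c(-5, 0, 5)) * 4L +
                  findInterval(g$u, c(-5, 0, 5))) + 1L
  g
})

#' Compute the 64-dimensional SURF descriptor of an oriented point
#'
#' Haar responses (window `2*scale`) are taken at 12 x 12 regularly spaced
#' sample points over an oriented window of side `20*scale`, rotated into the
#' point's frame and Gaussian-weighted (`sigma = 3.3*scale`). Each of the
#' 4 x 4 subregions sums its 3 x 3 samples into
#' `(sum dx, sum dy, sum |dx|, sum |dy|)`; the 64-vector is L2-normalised
#' (a flat region yields the all-zero vector).
#'
#' @inheritParams assignOrientation
#' @param orientation dominant orientation in radians.
#' @return Numeric vector of length 64 with unit L2 norm (or all zeros).
#' @export
computeDescriptor <- function(ii, x, y, scale, orientation) {
  s <- scale
  w <- 2L * max(1L, as.integer(round(s)))
  co <- cos(orientation); si <- sin(orientation)
  gx <- as.integer(round(x + (descriptorGrid$u * co - descriptorGrid$v * si) * s))
  gy <- as.integer(round(y + (descriptorGrid$u * si + descriptorGrid$v * co) * s))
  rdx <- haarX(ii, gy, gx, w)
  rdy <- haarY(ii, gy, gx, w)
  # rotate gradients into the descriptor frame, then weight
  g <- exp(-(descriptorGrid$u^2 + descriptorGrid$v^2) * s^2 / (2 * (3.3 * s)^2))
  dx <- ( co * rdx + si * rdy) * g
  dy <- (-si * rdx + co * rdy) * g
  desc <- numeric(64L)
  for (q in seq_len(16L)) {
    sel <- descriptorGrid$subregion == q
    desc[(q - 1L) * 4L + 1:4] <- c(sum(dx[sel]), sum(dy[sel]),
                                   sum(abs(dx[sel])), sum(abs(dy[sel])))
  }
  n <- sqrt(sum(desc^2))
  if (n > 0) desc / n else desc
}

# Margin (pixels) a point needs from every border: the orientation sampling
# ring of radius 6*scale must fit. Haar windows that overhang the border
# (including descriptor samples of large-scale points) are clipped by the
# integral-image border policy rather than skipped.
surfMargin <- function(scale) {
  6L * max(1L, as.integer(round(scale)))
}

#' Extract SURF descriptors from an image
#'
#' Full local-feature pass: interest-point detection, margin filtering
#' (points whose orientation sampling ring of radius `6*scale` does not fit
#' are skipped; descriptor samples overhanging the border are clipped),
#' orientation assignment, and descriptor extraction.
#'
#' @param image `SeedImage`, RGB array, or grayscale matrix.
#' @param threshold,octaves,levels passed to [detectInterestPoints()].
#' @param maxPoints keep at most this many strongest points (default 200).
#' @return List with `points` (data.frame: x, y, scale, response, laplacian,
#'   orientation) and `descriptors` (`n x 64` matrix; zero rows if nothing
#'   was detected).
#' @export
extractSurfFeatures <- function(image, threshold = 4e-4, octaves = 3L,
                                levels = 4L, maxPoints = 200L) {
  gray <- if (is.matrix(image)) image else toGrayscale(image)
  pts <- detectInterestPoints(gray, threshold = threshold, octaves = octaves,
                              levels = levels)
  H <- nrow(gray); W <- ncol(gray)
  if (nrow(pts) > 0L) {
    m <- vapply(pts$scale, surfMargin, numeric(1))
    keep <- pts$x > m & pts$x <= W - m & pts$y > m & pts$y <= H - m
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) > maxPoints) pts <- pts[seq_len(maxPoints), , drop = FALSE]
  ii <- integralImage(gray)
  n <- nrow(pts)
  desc <- matrix(0, n, 64L)
  ori <- numeric(n)
  for (i in seq_len(n)) {
    ori[i] <- assignOrientation(ii, pts$x[i], pts$y[i], pts$scale[i])
    desc[i, ] <- computeDescriptor(ii, pts$x[i], pts$y[i], pts$scale[i], ori[i])
  }
  pts$orientation <- ori
  rownames(pts) <- NULL
  list(points = pts, descriptors = desc)
}
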