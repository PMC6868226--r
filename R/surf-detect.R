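#' Convert RGB to grayscale intensity
#'
#' Weighted channel sum using the Y (luminance) row of the package's
#' RGB-to-XYZ matrix: `0.2126 R + 0.7152 G + 0.0722 B`, so the intensity
#' model is coherent with the colour pipeline.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]` or a `SeedImage`.
#' @return `H x W` numeric matrix.
#' @export
toGrayscale <- function(image) {
  px <- if (is(image, "SeedImage")) pixels(image) else image
  stopIfNot3Channel(px)
  0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}

#' Integral image
#'
#' Cumulative-sum table of size `(H+1) x (W+1)` with a zero first row and
#' column, so any rectangular pixel sum costs four lookups ([boxSum()]).
#'
#' @param gray `H x W` numeric matrix.
#' @return `(H+1) x (W+1)` matrix; the bottom-right entry is the total sum.
#' @export
integralImage <- function(gray) {
  if (!is.matrix(gray)) stop("gray must be a matrix")
  if (any(!is.finite(gray))) stop("image must be finite")
  H <- nrow(gray); W <- ncol(gray)
  ii <- matrix(0, H + 1L, W + 1L)
  ii[-1L, -1L] <- t(apply(apply(gray, 2L, cumsum), 1L, cumsum))
  ii
}

#' Rectangular pixel sum from an integral image
#'
#' Sum of the pixel block starting at `(row, col)` (1-based, inclusive) with
#' the given extent. Out-of-bounds parts of the rectangle are clipped to the
#' image, so border filters degrade gracefully.
#'
#' @param ii integral image from [integralImage()].
#' @param row,col 1-based top-left corner; may be vectors (equal length).
#' @param rows,cols block extent in pixels (scalars).
#' @return Numeric vector of block sums.
#' @export
boxSum <- function(ii, row, col, rows, cols) {
  H <- nrow(ii) - 1L; W <- ncol(ii) - 1L
  y0 <- clamp(row - 1L, 0L, H); y1 <- clamp(row + rows - 1L, 0L, H)
  x0 <- clamp(col - 1L, 0L, W); x1 <- clamp(col + cols - 1L, 0L, W)
  ii[cbind(y1 + 1L, x1 + 1L)] - ii[cbind(y0 + 1L, x1 + 1L)] -
    ii[cbind(y1 + 1L, x0 + 1L)] + ii[cbind(y0 + 1L, x0 + 1L)]
}

# Box-filter Hessian responses (determinant and trace) for one filter size L
# at the given pixel rows r / cols c (vectors of equal length, 1-based).
# The mixed second derivative carries the usual 0.9 weight compensating the
# box approximation: det = Dxx*Dyy - (0.9*Dxy)^2.
hessianResponse <- function(ii, r, c, L) {
  l <- L %/% 3L                 # lobe
  b <- (L - 1L) %/% 2L          # border
  inv <- 1 / (L * L)
  Dxx <- (boxSum(ii, r - l + 1L, c - b, 2L * l - 1L, L) -
          3 * boxSum(ii, r - l + 1L, c - l %/% 2L, 2L * l - 1L, l)) * inv
  Dyy <- (boxSum(ii, r - b, c - l + 1L, L, 2L * l - 1L) -
          3 * boxSum(ii, r - l %/% 2L, c - l + 1L, l, 2L * l - 1L)) * inv
  Dxy <- (boxSum(ii, r - l, c + 1L, l, l) +
          boxSum(ii, r + 1L, c - l, l, l) -
          boxSum(ii, r - l, c - l, l, l) -
          boxSum(ii, r + 1L, c + 1L, l, l)) * inv
  list(det = Dxx * Dyy - 0.81 * Dxy * Dxy, trace = Dxx + Dyy)
}

#' Detect SURF interest points
#'
#' Blob detection by the box-filter approximation of the Hessian determinant
#' over a scale space of `octaves` octaves with `levels` filter sizes each
#' (initial 9x9 filter, sampling stride doubling per octave). Interest points
#' are strict 3x3x3 local maxima in (x, y, scale) above `threshold`, tagged
#' with the sign of the box-filter Laplacian (`Dxx + Dyy`): `+1` for dark
#' blobs on a bright background, `-1` for the reverse. Maxima are not
#' interpolated, which keeps detection fully deterministic.
#'
#' @param gray `H x W` grayscale matrix in `[0, 1]` (or an RGB array /
#'   `SeedImage`, converted via [toGrayscale()]).
#' @param threshold Hessian-determinant threshold (default `4e-4`, tuned for
#'   intensities in `[0, 1]`).
#' @param octaves,levels scale-space extent (defaults 3 and 4).
#' @return `data.frame` with columns `x`, `y` (pixel coordinates, 1-based),
#'   `scale`, `response`, `laplacian` (+1/-1), sorted by descending response.
#'   A constant image yields zero rows.
#' @export
detectInterestPoints <- function(gray, threshold = 4e-4, octaves = 3L,
                                 levels = 4L) {
  if (length(dim(gray)) == 3L || is(gray, "SeedImage")) gray <- toGrayscale(gray)
  H <- nrow(gray); W <- ncol(gray)
  if (H < 32L || W < 32L) stop("image must be at least 32 x 32")
  ii <- integralImage(gray)
  out <- list()
  for (o in seq_len(octaves)) {
    step <- 2L^(o - 1L)
    rs <- seq(1L, H, by = step)
    cs <- seq(1L, W, by = step)
    nr <- length(rs); nc <- length(cs)
    rg <- rep(rs, times = nc); cg <- rep(cs, each = nr)
    sizes <- 3L * (2L^o * seq_len(levels) + 1L)
    det <- array(0, c(nr, nc, levels))
    trc <- array(0, c(nr, nc, levels))
    for (i in seq_len(levels)) {
      h <- hessianResponse(ii, rg, cg, sizes[i])
      det[, , i] <- h$det
      trc[, , i] <- h$trace
    }
    for (m in 2L:(levels - 1L)) {
      # margin: largest filter of the triple must fit inside the image
      bmax <- (sizes[m + 1L] - 1L) %/% 2L
      marg <- (bmax %/% step) + 1L
      ri <- (marg + 1L):(nr - marg); ci <- (marg + 1L):(nc - marg)
      if (length(ri) < 1L || length(ci) < 1L) next
      mid <- det[, , m]
      cand <- mid[ri, ci] > threshold
      if (!any(cand)) next
      for (dl in -1L:1L) {
        layer <- det[, , m + dl]
        for (dy in -1L:1L) for (dx in -1L:1L) {
          if (dl == 0L && dy == 0L && dx == 0L) next
          cand <- cand & (mid[ri, ci] > layer[ri + dy, ci + dx])
          if (!any(cand)) break
        }
        if (!any(cand)) break
      }
      if (!any(cand)) next
      idx <- which(cand, arr.ind = TRUE)
      pr <- ri[idx[, 1]]; pc <- ci[idx[, 2]]
      out[[length(out) + 1L]] <- data.frame(
        x = cs[pc], y = rs[pr],
        scale = 1.2 * sizes[m] / 9,
        response = mid[cbind(pr, pc)],
        laplacian = ifelse(trc[cbind(pr, pc, rep(m, nrow(idx)))] >= 0, 1L, -1L))
    }
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(), y = numeric(), scale = numeric(),
                      response = numeric(), laplacian = integer()))
  pts <- do.call(rbind, out)
  pts <- pts[order(-pts$response, pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}
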