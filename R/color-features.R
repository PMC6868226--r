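# RGB -> XYZ transfer matrix (rows X, Y, Z). Applied to raw [0,1] RGB; see
# the methods vignette for why no gamma linearisation is applied by default.
RGB2XYZ <- matrix(c(0.4124, 0.3576, 0.1805,
                    0.2126, 0.7152, 0.0722,
                    0.0193, 0.1192, 0.9505),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))

# Piecewise f(t) of the L*a*b* transform: cube root above the knee, a linear
# segment below. Constants kept exactly as used by the grading model (they
# differ slightly in precision from the CIE standard values).
LAB_KNEE <- 0.0089
LAB_SLOPE <- 7.7870
LAB_OFFSET <- 0.1379

#' Reference white point
#'
#' XYZ tristimulus of RGB white `(1, 1, 1)` under the package's RGB-to-XYZ
#' matrix: `(0.9505, 1.0000, 1.0890)`. Using this white makes RGB white map
#' to `L* = 100` under the model's own matrix.
#'
#' @return Named numeric triple `(X, Y, Z)`.
#' @export
referenceWhite <- function() {
  w <- as.numeric(RGB2XYZ %*% c(1, 1, 1))
  names(w) <- c("X", "Y", "Z")
  w
}

#' Convert RGB to CIE XYZ
#'
#' Per-pixel linear map of `[0, 1]` RGB intensities to CIE XYZ tristimulus
#' values. By default the matrix is applied to the raw intensities; set
#' `linearize = TRUE` to remove an sRGB gamma encoding first.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`, or a length-3 RGB vector.
#' @param linearize apply sRGB inverse-gamma before the matrix.
#' @return Array (or vector) of the same shape holding X, Y, Z.
#' @examples
#' rgbToXyz(c(1, 0, 0))   # (0.4124, 0.2126, 0.0193)
#' @export
rgbToXyz <- function(image, linearize = FALSE) {
  vec <- is.null(dim(image))
  if (vec) {
    if (length(image) != 3L) stop("expected a length-3 RGB vector")
    image <- array(image, c(1L, 1L, 3L))
  }
  stopIfNot3Channel(image)
  if (min(image) < 0 || max(image) > 1) stop("RGB intensities must lie in [0, 1]")
  if (linearize) {
    image <- ifelse(image <= 0.04045, image / 12.92,
                    ((image + 0.055) / 1.055)^2.4)
  }
  d <- dim(image)
  flat <- matrix(image, ncol = 3L)        # pixels x (R,G,B)
  xyz <- flat %*% t(RGB2XYZ)
  out <- array(xyz, d)
  if (vec) as.numeric(out[1, 1, ]) else out
}

labF <- function(t) {
  ifelse(t > LAB_KNEE, t^(1 / 3), LAB_SLOPE * t + LAB_OFFSET)
}

#' Convert XYZ to CIE L*a*b*
#'
#' Applies the L*a*b* transform relative to a reference white. `L*` is
#' lightness (about `[0, 100]`), `a*` green-red and `b*` blue-yellow.
#'
#' @param xyz `H x W x 3` XYZ array or length-3 vector.
#' @param white XYZ triple of the reference white; all components must be
#'   strictly positive. Defaults to [referenceWhite()].
#' @return Array (or vector) of the same shape holding L*, a*, b*.
#' @export
xyzToLab <- function(xyz, white = referenceWhite()) {
  if (any(white <= 0)) stop("reference white components must be strictly positive")
  vec <- is.null(dim(xyz))
  if (vec) xyz <- array(xyz, c(1L, 1L, 3L))
  stopIfNot3Channel(xyz)
  fx <- labF(xyz[, , 1] / white[1])
  fy <- labF(xyz[, , 2] / white[2])
  fz <- labF(xyz[, , 3] / white[3])
  out <- array(c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz)), dim(xyz))
  if (vec) as.numeric(out[1, 1, ]) else out
}

#' Convert RGB to L*a*b*
#'
#' Convenience composition of [rgbToXyz()] and [xyzToLab()].
#'
#' @inheritParams rgbToXyz
#' @param white reference white passed to [xyzToLab()].
#' @return L*a*b* array of the same shape.
#' @export
rgbToLab <- function(image, white = referenceWhite(), linearize = FALSE) {
  xyzToLab(rgbToXyz(image, linearize = linearize), white = white)
}

#' Convert RGB to HSI
#'
#' Geometric hue/saturation/intensity conversion used by the HSI baseline.
#' Hue is returned on `[0, 1)` (cyclic, red at 0), saturation and intensity
#' on `[0, 1]`. Achromatic pixels get `S = 0` and, by convention, `H = 0`.
#'
#' @inheritParams rgbToXyz
#' @return `H x W x 3` array (or length-3 vector) of H, S, I.
#' @export
rgbToHsi <- function(image) {
  vec <- is.null(dim(image))
  if (vec) image <- array(image, c(1L, 1L, 3L))
  stopIfNot3Channel(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(clamp(ifelse(den > 0, num / den, 1), -1, 1))
  h <- ifelse(b > g, 2 * pi - theta, theta) / (2 * pi)
  h[s == 0] <- 0
  h[h >= 1] <- 0
  out <- array(c(h, s, i), dim(image))
  if (vec) as.numeric(out[1, 1, ]) else out
}

#' Extract spatial colour-patch features
#'
#' Tiles the image into non-overlapping `tile x tile` pixel blocks (partial
#' edge blocks are dropped) and describes each block by its three per-channel
#' means plus the block-centre coordinates normalised to `[0, 1]` by image
#' width and height — a 5-dimensional feature combining colour and spatial
#' layout.
#'
#' @param channels `H x W x 3` array in any colour space (L*a*b* for the
#'   joint model; RGB or HSI for the baselines).
#' @param tile tile side in pixels (default 16).
#' @return `n x 5` matrix, columns `(c1, c2, c3, x, y)`; one row per tile.
#' @export
extractColorPatchFeatures <- function(channels, tile = 16L) {
  stopIfNot3Channel(channels)
  d <- dim(channels)
  ny <- d[1] %/% tile
  nx <- d[2] %/% tile
  if (ny < 1L || nx < 1L)
    stop("image (", d[1], " x ", d[2], ") is smaller than one ",
         tile, " x ", tile, " tile")
  feats <- matrix(0, ny * nx, 5L)
  row <- 1L
  for (jy in seq_len(ny)) {
    ys <- ((jy - 1L) * tile + 1L):(jy * tile)
    for (jx in seq_len(nx)) {
      xs <- ((jx - 1L) * tile + 1L):(jx * tile)
      blk <- channels[ys, xs, , drop = FALSE]
      feats[row, 1:3] <- colMeans(matrix(blk, ncol = 3L))
      # block centre, normalised by full image width/height
      feats[row, 4] <- ((jx - 0.5) * tile) / d[2]
      feats[row, 5] <- ((jy - 0.5) * tile) / d[1]
      row <- row + 1L
    }
  }
  colnames(feats) <- c("c1", "c2", "c3", "x", "y")
  feats
}

#' Per-image colour features in a chosen colour space
#'
#' Converts a [SeedImage-class] (or raw array) to the requested colour space
#' and extracts the spatial patch features.
#'
#' @param image a `SeedImage` or `H x W x 3` RGB array in `[0, 1]`.
#' @param colorspace one of `"lab"`, `"rgb"`, `"hsi"`.
#' @param tile tile side in pixels.
#' @return `n x 5` feature matrix.
#' @export
colorFeatures <- function(image, colorspace = c("lab", "rgb", "hsi"),
                          tile = 16L) {
  colorspace <- match.arg(colorspace)
  px <- if (is(image, "SeedImage")) pixels(image) else image
  channels <- switch(colorspace,
    lab = rgbToLab(px),
    rgb = px,
    hsi = rgbToHsi(px))
  extractColorPatchFeatures(channels, tile = tile)
}
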