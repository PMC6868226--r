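#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif predict sd
#' @importFrom utils head write.csv read.csv
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic stages go through this so no global RNG state leaks.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stage label; keeps all stage
# seeds distinct, reproducible, and inside the 32-bit integer range.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Round half away from zero (base round() rounds half to even); percentages
# compared against printed values use this mode.
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Rec. 709 / XYZ Y-row luminance of an H x W x 3 array or length-3 vector.
luminance <- function(rgb) {
  if (is.null(dim(rgb))) sum(c(0.2126, 0.7152, 0.0722) * rgb)
  else 0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
}

stopIfNot3Channel <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("expected an H x W x 3 array, got dimensions ",
         paste(dim(pixels), collapse = " x "))
  invisible(pixels)
}
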