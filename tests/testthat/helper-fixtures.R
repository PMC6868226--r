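# Shared in-code fixtures: small synthetic scenes and independent oracles.

# Gaussian blob scene: dark (or bright) blob on the opposite background.
blobImage <- function(size = 96L, cx = 48, cy = 48, sigma = 4,
                      dark = TRUE, amplitude = 0.7) {
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), times = size), size, size)
  g <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  if (dark) 0.9 - amplitude * g else 0.2 + amplitude * g
}

# Scene with several blobs for detection-stability checks.
multiBlobImage <- function(size = 128L, seed = 42L) {
  centers <- matrix(c(30, 30, 90, 40, 50, 90, 100, 100), ncol = 2, byrow = TRUE)
  img <- matrix(0.85, size, size)
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), times = size), size, size)
  for (i in seq_len(nrow(centers))) {
    img <- img - 0.6 * exp(-((x - centers[i, 1])^2 + (y - centers[i, 2])^2) /
                             (2 * (3 + i)^2))
  }
  pmin(pmax(img, 0), 1)
}

# Rotate a matrix 90 degrees counter-clockwise: (x, y) -> (y, W + 1 - x).
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Map original pixel coordinates into the rot90ccw-rotated image.
rot90ccwCoords <- function(x, y, W) list(x = y, y = W + 1 - x)

# Independent scalar HSI conversion (geometric formulas, one pixel).
hsiOracle <- function(r, g, b) {
  i <- (r + g + b) / 3
  mn <- min(r, g, b)
  s <- if (i > 0) 1 - mn / i else 0
  if (s == 0) return(c(0, 0, i))
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(max(-1, min(1, num / den)))
  h <- if (b > g) 2 * pi - theta else theta
  h <- h / (2 * pi)
  if (h >= 1) h <- 0
  c(h, s, i)
}

# Exhaustive 2-means oracle on 1-D points: best WCSS over all bipartitions.
twoMeansOracle <- function(pts) {
  n <- length(pts)
  best <- NULL; bestW <- Inf
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    c1 <- mean(pts[sel]); c2 <- mean(pts[!sel])
    w <- sum((pts[sel] - c1)^2) + sum((pts[!sel] - c2)^2)
    if (w < bestW) { bestW <- w; best <- sort(c(c1, c2)) }
  }
  best
}

# Random labeled feature set: three well-separated 2-D Gaussian clusters.
separableClusters <- function(n = 30L, sigma = 0.1, seed = 11L) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  lab <- rep(c("good", "moderate", "unhealthy"), length.out = n)
  idx <- as.integer(factor(lab, levels = c("good", "moderate", "unhealthy")))
  x <- centers[idx, ] + matrix(rnorm(2 * n, 0, sigma), n, 2)
  list(features = x, labels = lab)
}

# Reference confusion-matrix counts of a canonical three-grade soybean
# experiment (197 training / 84 test kernels per class), in this package's
# convention (rows = predicted, columns = actual).
trainCounts <- matrix(c(197, 5, 1,
                        0, 179, 7,
                        0, 13, 189), nrow = 3, byrow = TRUE,
                      dimnames = list(c("good", "moderate", "unhealthy"),
                                      c("good", "moderate", "unhealthy")))
testCounts <- matrix(c(84, 5, 1,
                       0, 53, 13,
                       0, 26, 70), nrow = 3, byrow = TRUE,
                     dimnames = list(c("good", "moderate", "unhealthy"),
                                     c("good", "moderate", "unhealthy")))

# Expand a confusion matrix into (predicted, actual) label vectors.
labelsFromCounts <- function(cts) {
  pred <- character(0); act <- character(0)
  for (i in rownames(cts)) for (j in colnames(cts)) {
    pred <- c(pred, rep(i, cts[i, j]))
    act <- c(act, rep(j, cts[i, j]))
  }
  list(predicted = pred, actual = act)
}
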