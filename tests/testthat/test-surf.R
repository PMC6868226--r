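test_that("grayscale conversion uses the luminance weights", {
  expect_equal(toGrayscale(array(1, c(32, 32, 3)))[1, 1], 1.0)
  expect_equal(toGrayscale(array(0, c(32, 32, 3)))[1, 1], 0)
  g <- array(0, c(32, 32, 3)); g[, , 2] <- 1
  expect_equal(toGrayscale(g)[5, 7], 0.7152)
})

test_that("integral image reproduces every rectangle sum exactly", {
  ones <- matrix(1, 2, 2)
  ii <- integralImage(ones)
  expect_equal(boxSum(ii, 1, 1, 2, 2), 4)
  set.seed(4)
  m <- matrix(runif(64), 8, 8)
  ii <- integralImage(m)
  expect_equal(ii[9, 9], sum(m))
  for (r1 in 1:8) for (r2 in r1:8) for (c1 in 1:8) for (c2 in c1:8) {
    expect_equal(boxSum(ii, r1, c1, r2 - r1 + 1, c2 - c1 + 1),
                 sum(m[r1:r2, c1:c2]))
  }
  # clipped rectangles degrade to the in-bounds part
  expect_equal(boxSum(ii, -3, -3, 12, 12), sum(m))
  expect_equal(boxSum(ii, -5, 1, 3, 8), 0)
})

test_that("blob polarity sets the Laplacian sign and constants give nothing", {
  expect_equal(nrow(detectInterestPoints(matrix(0.7, 64, 64))), 0L)
  dark <- blobImage(dark = TRUE)
  pts <- detectInterestPoints(dark)
  expect_gte(nrow(pts), 1L)
  d <- sqrt((pts$x - 48)^2 + (pts$y - 48)^2)
  expect_lte(min(d), 2)
  expect_equal(pts$laplacian[which.min(d)], 1L)
  bright <- blobImage(dark = FALSE)
  ptsB <- detectInterestPoints(bright)
  dB <- sqrt((ptsB$x - 48)^2 + (ptsB$y - 48)^2)
  expect_equal(ptsB$laplacian[which.min(dB)], -1L)
})

test_that("contrast inversion flips every sign and keeps locations", {
  img <- multiBlobImage()
  a <- detectInterestPoints(img)
  b <- detectInterestPoints(1 - img)
  expect_equal(nrow(a), nrow(b))
  # same determinant responses, so same ordering: compare row-wise
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$laplacian, -b$laplacian)
})

test_that("detection is stable under mild additive noise", {
  img <- multiBlobImage()
  base <- detectInterestPoints(img)
  set.seed(9)
  noisy <- pmin(pmax(img + matrix(rnorm(length(img), 0, 0.01),
                                  nrow(img)), 0), 1)
  re <- detectInterestPoints(noisy)
  hit <- vapply(seq_len(nrow(base)), function(i) {
    any((re$x - base$x[i])^2 + (re$y - base$y[i])^2 <= 4)
  }, logical(1))
  expect_gte(mean(hit), 0.7)
})

test_that("orientation follows the gradient of a step edge", {
  # vertical edge, intensity increasing with x: gradient points along +x
  ramp <- pmin(pmax((seq_len(64) - 32) / 4, 0), 1)
  img <- matrix(rep(ramp, each = 64), 64, 64)
  ii <- integralImage(img)
  th <- assignOrientation(ii, x = 33, y = 32, scale = 2)
  delta <- min(abs(th - 0), abs(th - 2 * pi))
  expect_lt(delta, 15 * pi / 180)
})

test_that("orientation shifts with image rotation", {
  # anisotropic scene (blob plus satellite) so the dominant orientation is
  # well defined; an isotropic blob's orientation is a degenerate tie
  x <- matrix(rep(1:96, each = 96), 96, 96)
  y <- matrix(rep(1:96, times = 96), 96, 96)
  img <- 0.9 - 0.7 * exp(-((x - 48)^2 + (y - 48)^2) / (2 * 16)) -
    0.45 * exp(-((x - 62)^2 + (y - 48)^2) / (2 * 9))
  img <- pmin(pmax(img, 0), 1)
  f <- extractSurfFeatures(img, maxPoints = 5)
  expect_gte(nrow(f$points), 1L)
  rot <- rot90ccw(img)
  fr <- extractSurfFeatures(rot, maxPoints = 20)
  p <- f$points[1, ]
  rc <- rot90ccwCoords(p$x, p$y, ncol(img))
  j <- which.min((fr$points$x - rc$x)^2 + (fr$points$y - rc$y)^2)
  expect_lt(sqrt((fr$points$x[j] - rc$x)^2 + (fr$points$y[j] - rc$y)^2), 3)
  dth <- (fr$points$orientation[j] - p$orientation) %% (2 * pi)
  # counter-clockwise quarter-turn of the scene shifts orientation by 3*pi/2
  # in row-down image coordinates
  expect_lt(min(abs(dth - 3 * pi / 2), abs(dth - 3 * pi / 2 + 2 * pi),
                abs(dth - 3 * pi / 2 - 2 * pi)), 10 * pi / 180)
})

test_that("descriptors are 64-d, unit-norm or zero, and rotation-robust", {
  img <- multiBlobImage()
  f <- extractSurfFeatures(img, maxPoints = 10)
  expect_equal(ncol(f$descriptors), 64L)
  nrm <- sqrt(rowSums(f$descriptors^2))
  expect_true(all(abs(nrm - 1) < 1e-9 | nrm == 0))
  # flat region: all-zero descriptor
  flat <- integralImage(matrix(0.5, 96, 96))
  expect_equal(computeDescriptor(flat, 48, 48, 2, 0), rep(0, 64))
  # 90-degree rotation: matched descriptors stay similar
  rot <- rot90ccw(img)
  fr <- extractSurfFeatures(rot, maxPoints = 30)
  sims <- vapply(seq_len(min(5L, nrow(f$points))), function(i) {
    rc <- rot90ccwCoords(f$points$x[i], f$points$y[i], ncol(img))
    j <- which.min((fr$points$x - rc$x)^2 + (fr$points$y - rc$y)^2)
    sum(f$descriptors[i, ] * fr$descriptors[j, ])
  }, numeric(1))
  expect_gt(median(sims), 0.8)
})

test_that("interest points report in-bounds coordinates and exact signs", {
  img <- multiBlobImage()
  pts <- detectInterestPoints(img)
  expect_true(all(pts$x >= 1 & pts$x <= ncol(img)))
  expect_true(all(pts$y >= 1 & pts$y <= nrow(img)))
  expect_true(all(pts$laplacian %in% c(-1L, 1L)))
  expect_true(all(diff(pts$response) <= 0))
})
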