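test_that("k-means recovers trivial and exhaustively verified clusterings", {
  # n = k distinct points: every point becomes its own word
  set.seed(21)
  x <- matrix(rnorm(6 * 5), 6, 5)
  d <- buildDictionary(x, k = 6, seed = 1)
  expect_equal(nrow(words(d)), 6L)
  ordA <- do.call(order, as.data.frame(words(d)))
  ordB <- do.call(order, as.data.frame(x))
  expect_equal(unname(words(d)[ordA, ]), unname(x[ordB, ]), tolerance = 1e-12)
  # exhaustive 2-means oracle on 1-D points
  pts <- c(0, 0.1, 10, 10.1)
  oracle <- twoMeansOracle(pts)
  expect_equal(oracle, c(0.05, 10.05))
  d2 <- buildDictionary(cbind(pts, 0, 0, 0, 0), k = 2, seed = 3,
                        modality = "color")
  expect_equal(sort(words(d2)[, 1]), oracle)
  # full-scale default size
  expect_equal(eval(formals(buildDictionary)$k), 800L)
})

test_that("k-means objective is non-increasing and seeds reproduce exactly", {
  set.seed(22)
  x <- matrix(runif(200 * 5), 200, 5)
  d <- buildDictionary(x, k = 8, seed = 7)
  wcss <- attr(d, "wcss")
  expect_gte(length(wcss), 1L)
  expect_true(all(diff(wcss) <= 1e-8))
  d2 <- buildDictionary(x, k = 8, seed = 7)
  expect_identical(words(d), words(d2))
  # a different seed is allowed to find a different local optimum
  expect_error(buildDictionary(x[1:5, ], k = 8, seed = 1), "lower k")
})

test_that("k-means agrees with stats::kmeans on a well-separated instance", {
  set.seed(23)
  ctrs <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  x <- ctrs[rep(1:3, each = 40), ] + matrix(rnorm(240, 0, 0.2), 120, 2)
  x5 <- cbind(x, 0, 0, 0)
  d <- buildDictionary(x5, k = 3, seed = 2, modality = "color")
  km <- stats::kmeans(x5, centers = 3, nstart = 10)
  a <- words(d)[order(words(d)[, 1], words(d)[, 2]), 1:2]
  b <- km$centers[order(km$centers[, 1], km$centers[, 2]), 1:2]
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
})

test_that("histogram encoding matches a brute-force nearest-word count", {
  set.seed(24)
  dict <- buildDictionary(matrix(runif(40 * 5), 40, 5), k = 5, seed = 9)
  feats <- matrix(runif(20 * 5), 20, 5)
  h <- encodeHistogram(feats, dict)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # independent pairwise-distance oracle
  cnt <- integer(5)
  for (i in 1:20) {
    dists <- apply(words(dict), 1, function(w) sqrt(sum((feats[i, ] - w)^2)))
    cnt[which.min(dists)] <- cnt[which.min(dists)] + 1L
  }
  expect_equal(as.numeric(h), cnt / 20)
  # all features at one word give a one-hot histogram
  onehot <- encodeHistogram(matrix(rep(words(dict)[3, ], 4), 4, 5,
                                   byrow = TRUE), dict)
  expect_equal(as.numeric(onehot), c(0, 0, 1, 0, 0))
})

test_that("encoding is permutation-invariant and guards dimensions", {
  set.seed(25)
  dict <- buildDictionary(matrix(runif(30 * 5), 30, 5), k = 4, seed = 5)
  feats <- matrix(runif(15 * 5), 15, 5)
  h1 <- encodeHistogram(feats, dict)
  h2 <- encodeHistogram(feats[sample(15), ], dict)
  expect_equal(as.numeric(h1), as.numeric(h2))
  expect_error(encodeHistogram(matrix(0, 3, 4), dict), "dimension")
  expect_warning(z <- encodeHistogram(NULL, dict), "zero histogram")
  expect_equal(as.numeric(z), rep(0, 4))
})

test_that("joint descriptors concatenate colour-then-surf", {
  ch <- structure(c(0.25, 0.75), modality = "color")
  sh <- structure(c(0.1, 0.2, 0.7), modality = "surf")
  j <- joinDescriptors(ch, sh)
  expect_length(j, 5L)
  expect_equal(j[1:2], c(0.25, 0.75))
  expect_equal(j[3:5], c(0.1, 0.2, 0.7))
  zero <- structure(rep(0, 3), modality = "surf")
  j0 <- joinDescriptors(ch, zero)
  expect_equal(j0, c(0.25, 0.75, 0, 0, 0), ignore_attr = TRUE)
  expect_error(joinDescriptors(sh, ch), "color")
  # per-modality defaults give a 1600-long joint descriptor
  expect_length(joinDescriptors(structure(rep(1 / 800, 800), modality = "color"),
                                structure(rep(1 / 800, 800), modality = "surf")),
                1600L)
})
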