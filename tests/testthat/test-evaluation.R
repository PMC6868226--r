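test_that("confusion matrix counts predicted rows against actual columns", {
  lv <- labelsFromCounts(trainCounts)
  cm <- confusionMatrix(lv$predicted, lv$actual)
  expect_equal(counts(cm), trainCounts)
  expect_equal(unname(colSums(counts(cm))), rep(197L, 3))
  # all-correct predictions give a diagonal matrix
  cmD <- confusionMatrix(rep(SEED_GRADES, 4), rep(SEED_GRADES, 4))
  expect_equal(counts(cmD), diag(4L, 3),
               ignore_attr = TRUE)
  # swapping the arguments transposes
  cmT <- confusionMatrix(lv$actual, lv$predicted)
  expect_equal(counts(cmT), t(trainCounts))
  expect_error(confusionMatrix(c("good", "mystery"), c("good", "good")),
               "unknown")
})

test_that("accuracy reproduces the printed training and test percentages", {
  expect_equal(accuracy(trainCounts), 95.6)
  expect_equal(accuracy(testCounts), 82.1)
  expect_equal(accuracy(diag(5L, 3)), 100.0)
  expect_error(accuracy(matrix(0L, 3, 3)), "empty")
})

test_that("per-class precision and recall match the printed narrative", {
  prTrain <- perClassPrecisionRecall(trainCounts)
  expect_equal(prTrain$precision, c(97.0, 96.2, 93.6))
  expect_equal(prTrain$recall, c(100.0, 90.9, 95.9))
  expect_equal(prTrain$predictedTotal, c(203, 186, 202))
  prTest <- perClassPrecisionRecall(testCounts)
  expect_equal(prTest$precision, c(93.3, 80.3, 72.9))
  expect_equal(prTest$recall, c(100.0, 63.1, 83.3))
  # diagonal matrix: everything 100%
  prD <- perClassPrecisionRecall(diag(7L, 3))
  expect_true(all(prD$precision == 100) && all(prD$recall == 100))
  # zero denominators are flagged, not NaN
  m <- matrix(c(5L, 3L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE,
              dimnames = list(SEED_GRADES, SEED_GRADES))
  prZ <- perClassPrecisionRecall(m)
  expect_equal(prZ$precision[2:3], c(0, 0))
  expect_false(any(prZ$precisionDefined[2:3]))
})

test_that("average precision matches hand-computed and asymptotic values", {
  # perfect ranking
  expect_equal(averagePrecision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # hand-computed step area
  ap <- averagePrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(ap, 1 * 0.5 + (2 / 3) * 0.5, tolerance = 1e-12)
  # random scores on balanced labels: AP converges to prevalence
  set.seed(51)
  s <- runif(1e4); lab <- rep(c(TRUE, FALSE), 5e3)
  expect_equal(averagePrecision(s, lab), 0.5, tolerance = 0.02)
  expect_error(prCurve(c(1, 2), c(FALSE, FALSE)), "positive")
})

test_that("AP is invariant under strictly monotone score transforms", {
  set.seed(52)
  s <- rnorm(200); lab <- runif(200) < 0.4
  a0 <- averagePrecision(s, lab)
  expect_equal(averagePrecision(2 * s + 5, lab), a0)
  expect_equal(averagePrecision(exp(s), lab), a0)
  expect_equal(averagePrecision(atan(s), lab), a0)
})

test_that("accuracy decomposes into recall weighted by class prevalence", {
  for (cts in list(trainCounts, testCounts)) {
    pc <- perClassPrecisionRecall(cts, digits = NULL)
    recomposed <- sum(pc$recall * pc$actualTotal / sum(cts))
    expect_equal(accuracy(cts, digits = NULL), recomposed, tolerance = 1e-12)
  }
})

test_that("mAP averages one-vs-rest average precisions", {
  set.seed(53)
  n <- 90
  actual <- sample(SEED_GRADES, n, replace = TRUE)
  scores <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, SEED_GRADES))
  scores[cbind(seq_len(n), match(actual, SEED_GRADES))] <-
    scores[cbind(seq_len(n), match(actual, SEED_GRADES))] + 3
  res <- meanAveragePrecision(scores, actual)
  expect_equal(res$mAP, mean(res$perClass))
  expect_gt(res$mAP, 0.9)
  rep <- evaluatePredictions(SEED_GRADES[max.col(scores)], actual, scores)
  expect_equal(rep$mAP, res$mAP)
  expect_s4_class(rep$confusion, "ConfusionMatrix")
})

test_that("printed-share arithmetic follows from the count matrix", {
  # diagonal shares of all test samples and the moderate->unhealthy share
  expect_equal(jmbof:::roundHalfUp(100 * testCounts["good", "good"] /
                                     sum(testCounts)), 33.3)
  expect_equal(jmbof:::roundHalfUp(100 * testCounts["unhealthy", "moderate"] /
                                     sum(testCounts)), 10.3)
})
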