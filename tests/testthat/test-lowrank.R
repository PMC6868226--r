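test_that("soft thresholding implements the L1 proximal map", {
  expect_equal(softThreshold(1.5, 1), 0.5)
  expect_equal(softThreshold(-0.3, 1), 0)
  M <- matrix(c(-2, 0.4, 0, 3), 2, 2)
  expect_equal(softThreshold(M, 0), M)
  expect_equal(softThreshold(M, 0.5), matrix(c(-1.5, 0, 0, 2.5), 2, 2))
  expect_error(softThreshold(M, -1), "non-negative")
})

test_that("singular-value thresholding shrinks the spectrum", {
  D <- diag(c(3, 1, 0.2))
  out <- singularValueThreshold(D, 0.5)
  expect_equal(svd(out)$d, c(2.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(singularValueThreshold(D, 5), matrix(0, 3, 3))
  set.seed(31)
  M <- matrix(rnorm(70), 10, 7)
  sv <- svd(M)
  oracle <- sv$u %*% diag(pmax(sv$d - 0.8, 0)) %*% t(sv$v)
  expect_equal(singularValueThreshold(M, 0.8), oracle, tolerance = 1e-9)
  expect_error(singularValueThreshold(matrix(c(1, NA, 0, 1), 2, 2), 0.1),
               "finite")
})

test_that("robust PCA converges and handles the zero matrix", {
  z <- rpcaDecompose(matrix(0, 5, 4))
  expect_equal(lowRankPart(z), matrix(0, 5, 4))
  expect_equal(sparsePart(z), matrix(0, 5, 4))
  expect_equal(z@iterations, 1L)
  set.seed(32)
  Y <- tcrossprod(matrix(rnorm(60), 20, 3), matrix(rnorm(45), 15, 3))
  dec <- rpcaDecompose(Y)
  expect_true(dec@converged)
  expect_lte(dec@residual, 1e-6)
  expect_lt(max(abs(Y - lowRankPart(dec) - sparsePart(dec))) / max(abs(Y)),
            1e-5)
})

test_that("a planted low-rank + sparse matrix is recovered", {
  set.seed(33)
  n <- 120; r <- 4
  L <- tcrossprod(matrix(rnorm(n * r), n, r), matrix(rnorm(n * r), n, r))
  S <- matrix(0, n, n)
  idx <- sample(n * n, round(0.05 * n * n))
  S[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
  dec <- rpcaDecompose(L + S, lambda = 1 / sqrt(n))
  relErr <- sqrt(sum((lowRankPart(dec) - L)^2)) / sqrt(sum(L^2))
  expect_lt(relErr, 1e-3)
  sv <- svd(lowRankPart(dec), nu = 0, nv = 0)$d
  expect_equal(sum(sv > 1e-6 * sv[1]), r)
})

test_that("the objective converges to a value beating trivial feasible
           splits, and the solution scales equivariantly", {
  set.seed(34)
  Y <- tcrossprod(matrix(rnorm(40), 20, 2), matrix(rnorm(30), 15, 2)) +
    matrix(rbinom(300, 1, 0.05) * rnorm(300, 0, 1), 20, 15)
  dec <- rpcaDecompose(Y)
  obj <- attr(dec, "objective")
  # objective stabilises once the iterates become feasible
  tail5 <- utils::tail(obj, 5)
  expect_lt(max(abs(diff(tail5))), 1e-6 * obj[length(obj)])
  # and beats both trivial feasible pairs (X, E) = (Y, 0) and (0, Y)
  final <- obj[length(obj)]
  expect_lte(final, sum(svd(Y, nu = 0, nv = 0)$d) + 1e-6)
  expect_lte(final, dec@lambda * sum(abs(Y)) + 1e-6)
  for (cc in c(0.1, 3)) {
    decC <- rpcaDecompose(cc * Y, lambda = dec@lambda)
    expect_lt(max(abs(lowRankPart(decC) - cc * lowRankPart(dec))) /
                max(abs(lowRankPart(dec))), 1e-6)
  }
})

test_that("the low-rank basis captures the requested energy", {
  set.seed(35)
  n <- 60; r <- 5
  L <- tcrossprod(matrix(rnorm(n * r), n, r), matrix(rnorm(n * r), n, r))
  S <- matrix(0, n, n)
  idx <- sample(n * n, round(0.05 * n * n))
  S[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
  dec <- rpcaDecompose(L + S, lambda = 1 / sqrt(n))
  model <- fitLowRankBasis(dec, energy = 0.99)
  expect_equal(model@rank, r)
  expect_lt(max(abs(crossprod(model@basis) - diag(model@rank))), 1e-9)
  # energy = 1 keeps the numerical rank
  full <- fitLowRankBasis(dec, energy = 1)
  sv <- svd(lowRankPart(dec), nu = 0, nv = 0)$d
  expect_equal(full@rank, sum(sv > max(dim(L)) * .Machine$double.eps * sv[1]))
  expect_error(fitLowRankBasis(matrix(0, 4, 4)), "all-zero")
})

test_that("projection reduces dimension and preserves retained structure", {
  set.seed(36)
  L <- tcrossprod(matrix(rnorm(90), 30, 3), matrix(rnorm(60), 20, 3))
  model <- fitLowRankBasis(L, energy = 1)
  P <- projectDescriptors(model, L)
  expect_equal(nrow(P), model@rank)
  expect_equal(ncol(P), ncol(L))
  recon <- model@basis %*% P
  expect_lt(sqrt(sum((recon - L)^2)) / sqrt(sum(L^2)), 1e-9)
  expect_equal(projectDescriptors(model, matrix(0, 30, 1)),
               matrix(0, model@rank, 1))
  expect_error(projectDescriptors(model, matrix(0, 7, 2)), "dimension")
})
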