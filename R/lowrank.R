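#' Elementwise soft-thresholding
#'
#' Proximal operator of the L1 norm: `sign(m) * max(|m| - tau, 0)`.
#'
#' @param M numeric matrix or vector.
#' @param tau non-negative threshold.
#' @return Object of the same shape.
#' @export
softThreshold <- function(M, tau) {
  if (tau < 0) stop("tau must be non-negative")
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Singular-value thresholding
#'
#' Proximal operator of the nuclear norm: soft-thresholds the singular
#' values of `M` and reconstructs.
#'
#' @param M numeric matrix with finite entries.
#' @param tau non-negative threshold.
#' @return Matrix of the same dimensions.
#' @export
singularValueThreshold <- function(M, tau) {
  if (tau < 0) stop("tau must be non-negative")
  if (any(!is.finite(M))) stop("matrix must have finite entries")
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Low-rank + sparse decomposition (robust PCA)
#'
#' Solves `min ||X||_* + lambda * ||E||_1  s.t.  Y = X + E` by the inexact
#' augmented-Lagrangian method: alternating singular-value thresholding for
#' the low-rank part `X` and soft-thresholding for the sparse part `E`, with
#' a dual update and geometric penalty growth (`mu0 = 1.25/||Y||_2`,
#' `rho = 1.5`). Iterates until the relative constraint residual
#' `||Y - X - E||_F / ||Y||_F` drops below `tol`.
#'
#' Applied to a joint visual-word descriptor matrix (columns = images) this
#' separates the shared low-dimensional structure `X` from sparse
#' per-image deviations `E`; `X` is the denoised representation used for
#' classification.
#'
#' @param Y `d x n` numeric matrix (columns are samples).
#' @param lambda sparse-part weight; default `1/sqrt(max(d, n))`.
#' @param tol relative residual tolerance (default `1e-7`).
#' @param maxIter outer iteration cap (default 500); hitting it sets
#'   `converged = FALSE` with a warning.
#' @return A [DecompositionResult-class].
#' @export
rpcaDecompose <- function(Y, lambda = NULL, tol = 1e-7, maxIter = 500L) {
  Y <- as.matrix(Y)
  if (length(Y) == 0L) stop("Y must be non-empty")
  if (any(!is.finite(Y))) stop("Y must have finite entries")
  d <- nrow(Y); n <- ncol(Y)
  if (is.null(lambda)) lambda <- 1 / sqrt(max(d, n))
  if (lambda <= 0) stop("lambda must be positive")
  normY <- sqrt(sum(Y^2))
  if (normY == 0) {
    return(new("DecompositionResult", X = Y * 0, E = Y * 0,
               lambda = lambda, iterations = 1L, residual = 0,
               converged = TRUE))
  }
  norm2 <- svd(Y, nu = 0L, nv = 0L)$d[1]
  normInf <- max(abs(Y))
  Z <- Y / max(norm2, normInf / lambda)   # dual variable
  mu <- 1.25 / norm2
  muMax <- mu * 1e7
  rho <- 1.5
  X <- matrix(0, d, n); E <- matrix(0, d, n)
  iter <- 0L; resid <- Inf
  objective <- numeric(0)
  while (iter < maxIter) {
    iter <- iter + 1L
    X <- singularValueThreshold(Y - E + Z / mu, 1 / mu)
    E <- softThreshold(Y - X + Z / mu, lambda / mu)
    R <- Y - X - E
    Z <- Z + mu * R
    mu <- min(mu * rho, muMax)
    resid <- sqrt(sum(R^2)) / normY
    objective[iter] <- sum(svd(X, nu = 0L, nv = 0L)$d) + lambda * sum(abs(E))
    if (resid <= tol) break
  }
  converged <- resid <= tol
  if (!converged)
    warning("rpcaDecompose did not converge in ", maxIter,
            " iterations (residual ", signif(resid, 3), ")")
  out <- new("DecompositionResult", X = X, E = E, lambda = lambda,
             iterations = iter, residual = resid, converged = converged)
  attr(out, "objective") <- objective  # ||X||_* + lambda*||E||_1 per iteration
  out
}

#' Fit an orthonormal basis for the denoised descriptor space
#'
#' Takes the SVD of a (converged) low-rank component and keeps the smallest
#' rank whose squared singular values capture at least `energy` of the
#' total; the corresponding left singular vectors form the projection basis
#' applied to both training and test descriptors.
#'
#' @param X low-rank matrix (`d x n`) or a [DecompositionResult-class].
#' @param energy squared-singular-value energy fraction to retain
#'   (default 0.99); `energy = 1` keeps the full numerical rank.
#' @return A [LowRankModel-class].
#' @export
fitLowRankBasis <- function(X, energy = 0.99) {
  if (is(X, "DecompositionResult")) X <- lowRankPart(X)
  X <- as.matrix(X)
  if (all(X == 0)) stop("cannot fit a basis on an all-zero matrix")
  if (energy <= 0 || energy > 1) stop("energy must lie in (0, 1]")
  sv <- svd(X)
  numRank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (energy == 1) r <- numRank
  else {
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    r <- which(cum >= energy)[1]
  }
  r <- max(1L, min(as.integer(r), numRank))
  new("LowRankModel", basis = sv$u[, seq_len(r), drop = FALSE],
      rank = r, singularValues = sv$d, energy = energy)
}

#' Project descriptors onto a low-rank basis
#'
#' Computes `t(basis) %*% D`; the same projection is applied to training and
#' test descriptors so the classifier sees a consistent feature space.
#'
#' @param model a [LowRankModel-class].
#' @param D `d x m` matrix of joint descriptors (columns = samples).
#' @return `r x m` matrix of reduced features.
#' @export
projectDescriptors <- function(model, D) {
  D <- as.matrix(D)
  if (nrow(D) != nrow(model@basis))
    stop("descriptor dimension ", nrow(D), " does not match basis (",
         nrow(model@basis), ")")
  crossprod(model@basis, D)
}
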