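#' Stratified train/test split
#'
#' Splits sample indices per class: `round(trainFraction * n_c)` of each
#' class go to training, the rest to test. With 281 samples per class and
#' the default fraction this yields the canonical 197 train / 84 test per
#' class (591 / 252 overall). Deterministic for a fixed seed.
#'
#' @param labels vector of class labels (one per sample).
#' @param trainFraction fraction per class assigned to training, in (0, 1).
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.7, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 members")
  train <- integer(0)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTrain <- round(trainFraction * length(idx))
      nTrain <- max(1L, min(nTrain, length(idx) - 1L))
      train <- c(train, sort(sample(idx, nTrain)))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# z-score with training statistics; constant dimensions get scale 1 so they
# pass through unchanged rather than dividing by zero.
fitScaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

applyScaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}

# Stratified fold assignment; remainders rotate across classes so overall
# fold sizes differ by at most 1.
makeFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  offset <- 0L
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fl <- ((seq_along(idx) + offset - 1L) %% k) + 1L
      folds[idx] <- sample(fl)
      offset <- offset + length(idx)
    }
  })
  folds
}

svmFit <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

#' Train the multiclass SVM grade classifier
#'
#' Features are z-scored with training statistics, then an RBF-kernel
#' one-vs-one multiclass SVM is fitted. The cost `C` and kernel width
#' `gamma` are selected by grid search under stratified k-fold
#' cross-validation (default 5-fold; set `cvFolds = "loo"` for leave-one-out,
#' i.e. k equal to the training size). Model selection sees only the
#' training data.
#'
#' @param features `n x p` numeric matrix.
#' @param labels length-`n` class labels (at least two distinct).
#' @param costGrid candidate costs (default `c(0.1, 1, 10, 100)`).
#' @param gammaGrid candidate kernel widths; default `2^(-4:2) / p`.
#' @param cvFolds folds for model selection: an integer or `"loo"`.
#' @param seed RNG seed for fold assignment.
#' @return List of class `"jmbofClassifier"` with elements `svm`, `scaler`,
#'   `classes`, `cost`, `gamma`, `cvAccuracy`.
#' @export
trainClassifier <- function(features, labels, costGrid = c(0.1, 1, 10, 100),
                            gammaGrid = NULL, cvFolds = 5L, seed = 1L) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("training needs at least two classes")
  p <- ncol(features)
  if (is.null(gammaGrid)) gammaGrid <- 2^(-4:2) / p
  scaler <- fitScaler(features)
  xs <- applyScaler(features, scaler)
  n <- nrow(xs)
  k <- if (identical(cvFolds, "loo")) n else as.integer(cvFolds)
  k <- max(2L, min(k, n))
  folds <- makeFolds(labels, k, deriveSeed(seed, "cvfolds"))
  grid <- expand.grid(cost = costGrid, gamma = gammaGrid)
  cvAcc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      held <- folds == f
      if (!any(held) || nlevels(droplevels(labels[!held])) < 2L) next
      fit <- svmFit(xs[!held, , drop = FALSE], droplevels(labels[!held]),
                    grid$cost[g], grid$gamma[g])
      pr <- predict(fit, xs[held, , drop = FALSE])
      correct <- correct + sum(as.character(pr) == as.character(labels[held]))
    }
    cvAcc[g] <- correct / n
  }
  best <- which.max(cvAcc)    # first maximum wins: fixed grid order
  fit <- svmFit(xs, labels, grid$cost[best], grid$gamma[best])
  structure(list(svm = fit, scaler = scaler, classes = levels(labels),
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cvAccuracy = cvAcc[best]),
            class = "jmbofClassifier")
}

#' Predict grades and per-class scores
#'
#' Applies the stored standardisation and the fitted SVM. Per-class scores
#' are built from the one-vs-one decision values by vote-margin aggregation
#' (each pairwise margin is added to the favoured class and subtracted from
#' the other), yielding one column per class usable for precision-recall
#' curves.
#'
#' @param model a classifier from [trainClassifier()].
#' @param features `m x p` matrix.
#' @return List with `labels` (character vector) and `scores`
#'   (`m x nClasses` matrix).
#' @export
predictGrades <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$scaler$center))
    stop("feature dimension ", ncol(features), " does not match model (",
         length(model$scaler$center), ")")
  xs <- applyScaler(features, model$scaler)
  pr <- predict(model$svm, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- matrix(0, nrow(xs), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  list(labels = as.character(pr), scores = scores)
}

#' k-fold cross-validation of the grade classifier
#'
#' Partitions the training samples into `k` stratified folds (with `k = n`,
#' the default, this is leave-one-out: every sample is validated exactly
#' once by a model fitted on the remaining `n - 1`), fits with fixed
#' hyperparameters on each complement, and reports per-fold and mean
#' accuracy.
#'
#' @param features `n x p` matrix.
#' @param labels length-`n` labels.
#' @param k number of folds, between 2 and `n`; default `n` (leave-one-out).
#' @param cost,gamma SVM hyperparameters (defaults: `cost = 10`,
#'   `gamma = 1/p`).
#' @param seed RNG seed for fold assignment.
#' @return List with `foldAccuracy`, `meanAccuracy`, `folds` (assignment
#'   vector), and `predictions`.
#' @export
crossValidate <- function(features, labels, k = nrow(as.matrix(features)),
                          cost = 10, gamma = NULL, seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels))
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must lie between 2 and n = ", n)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  scaler <- fitScaler(features)
  xs <- applyScaler(features, scaler)
  folds <- if (k == n) seq_len(n) else makeFolds(labels, k, deriveSeed(seed, "cv"))
  preds <- character(n)
  foldAcc <- numeric(k)
  for (f in seq_len(k)) {
    held <- folds == f
    fit <- svmFit(xs[!held, , drop = FALSE], droplevels(labels[!held]),
                  cost, gamma)
    pr <- as.character(predict(fit, xs[held, , drop = FALSE]))
    preds[held] <- pr
    foldAcc[f] <- mean(pr == as.character(labels[held]))
  }
  list(foldAccuracy = foldAcc, meanAccuracy = mean(preds == as.character(labels)),
       folds = folds, predictions = preds)
}
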