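#' Build a confusion matrix (rows = predicted, columns = actual)
#'
#' Entry `[i, j]` counts samples predicted as grade `i` whose actual grade
#' is `j`. This is the transpose of many toolkits' convention; all derived
#' quantities in this package use rows-as-predictions consistently.
#'
#' @param predicted,actual equal-length vectors of grade labels.
#' @param classes class order (default the three seed grades).
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(predicted, actual, classes = SEED_GRADES) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  bad <- setdiff(unique(c(predicted, actual)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  cts <- table(factor(predicted, classes), factor(actual, classes))
  m <- matrix(as.integer(cts), length(classes), length(classes),
              dimnames = list(classes, classes))
  new("ConfusionMatrix", counts = m)
}

# Accept either the S4 object or a raw rows-as-predictions count matrix.
asCounts <- function(cm) {
  if (is(cm, "ConfusionMatrix")) return(counts(cm))
  cm <- as.matrix(cm)
  if (is.null(rownames(cm))) {
    nm <- if (nrow(cm) == 3L) SEED_GRADES else paste0("class", seq_len(nrow(cm)))
    dimnames(cm) <- list(nm, nm)
  }
  cm
}

#' Overall classification accuracy
#'
#' `100 * trace / total` of a confusion matrix, optionally rounded half-up
#' to one decimal for comparison against printed percentages.
#'
#' @param cm a [ConfusionMatrix-class] or raw count matrix
#'   (rows = predicted).
#' @param digits decimals to round to (half-up); `NULL` for no rounding.
#' @return Accuracy percentage.
#' @export
accuracy <- function(cm, digits = 1) {
  cts <- asCounts(cm)
  total <- sum(cts)
  if (total == 0) stop("empty confusion matrix")
  acc <- 100 * sum(diag(cts)) / total
  if (is.null(digits)) acc else roundHalfUp(acc, digits)
}

#' Per-class precision and recall
#'
#' With rows as predictions, class precision is the diagonal over its row
#' total (`of everything predicted as the class, how much was right`) and
#' class recall the diagonal over its column total (`of everything actually
#' in the class, how much was found`). Zero denominators are reported as 0
#' with `defined = FALSE`.
#'
#' @inheritParams accuracy
#' @return `data.frame` with columns `class`, `precision`, `recall` (both in
#'   percent), `predictedTotal`, `actualTotal`, `precisionDefined`,
#'   `recallDefined`.
#' @export
perClassPrecisionRecall <- function(cm, digits = 1) {
  cts <- asCounts(cm)
  rowTot <- rowSums(cts); colTot <- colSums(cts)
  prec <- ifelse(rowTot > 0, 100 * diag(cts) / rowTot, 0)
  rec <- ifelse(colTot > 0, 100 * diag(cts) / colTot, 0)
  if (!is.null(digits)) {
    prec <- roundHalfUp(prec, digits); rec <- roundHalfUp(rec, digits)
  }
  data.frame(class = rownames(cts), precision = unname(prec),
             recall = unname(rec), predictedTotal = unname(rowTot),
             actualTotal = unname(colTot),
             precisionDefined = unname(rowTot > 0),
             recallDefined = unname(colTot > 0))
}

#' One-vs-rest precision-recall curve
#'
#' Sweeps every distinct score as a threshold (descending; tied scores are
#' grouped) and records precision and recall of the positive class at each.
#'
#' @param scores numeric scores, larger = more positive.
#' @param positives logical vector (or 0/1) marking positive samples.
#' @return `data.frame` with columns `threshold`, `precision`, `recall`.
#' @export
prCurve <- function(scores, positives) {
  positives <- as.logical(positives)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!any(positives)) stop("need at least one positive sample")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positives[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  data.frame(threshold = s[last],
             precision = tp / (tp + fp),
             recall = tp / sum(positives))
}

#' Average precision (step-wise area under the PR curve)
#'
#' `AP = sum_i precision_i * (recall_i - recall_{i-1})` over the threshold
#' sweep — the non-interpolated area under the precision-recall curve.
#'
#' @param curve output of [prCurve()], or scores when `positives` is given.
#' @param positives optional; when supplied, `curve` is taken as scores and
#'   the curve is computed first.
#' @return Average precision in `[0, 1]`.
#' @export
averagePrecision <- function(curve, positives = NULL) {
  if (!is.null(positives)) curve <- prCurve(curve, positives)
  dr <- diff(c(0, curve$recall))
  sum(curve$precision * dr)
}

#' Mean average precision over classes
#'
#' Unweighted mean of one-vs-rest average precisions, one per class.
#'
#' @param scores `n x nClasses` score matrix with class column names.
#' @param actual length-`n` vector of actual labels.
#' @param classes class order (default: score column names).
#' @return List with `perClass` (named AP vector) and `mAP`.
#' @export
meanAveragePrecision <- function(scores, actual, classes = colnames(scores)) {
  actual <- as.character(actual)
  ap <- vapply(classes, function(cl) {
    averagePrecision(scores[, cl], actual == cl)
  }, numeric(1))
  list(perClass = ap, mAP = mean(ap))
}

#' Full evaluation report for one model on one split
#'
#' Confusion matrix, overall accuracy, per-class precision/recall, per-class
#' PR curves and average precisions, and mAP.
#'
#' @param predicted predicted labels.
#' @param actual actual labels.
#' @param scores `n x nClasses` score matrix (optional; PR metrics are
#'   omitted when missing).
#' @param classes class order.
#' @return List of class `"jmbofReport"` with elements `confusion`,
#'   `accuracy`, `perClass`, `curves`, `averagePrecision`, `mAP`.
#' @export
evaluatePredictions <- function(predicted, actual, scores = NULL,
                                classes = SEED_GRADES) {
  cm <- confusionMatrix(predicted, actual, classes)
  rep <- list(confusion = cm, accuracy = accuracy(cm),
              perClass = perClassPrecisionRecall(cm),
              curves = NULL, averagePrecision = NULL, mAP = NA_real_)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    pr <- meanAveragePrecision(scores, actual, classes)
    rep$curves <- lapply(classes, function(cl)
      prCurve(scores[, cl], as.character(actual) == cl))
    names(rep$curves) <- classes
    rep$averagePrecision <- pr$perClass
    rep$mAP <- pr$mAP
  }
  class(rep) <- "jmbofReport"
  rep
}

#' @export
print.jmbofReport <- function(x, ...) {
  show(x$confusion)
  cat(sprintf("accuracy: %.1f%%", x$accuracy))
  if (!is.na(x$mAP)) cat(sprintf("  mAP: %.3f", x$mAP))
  cat("\n")
  invisible(x)
}
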