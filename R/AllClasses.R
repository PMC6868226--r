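#' Seed grade levels
#'
#' Appearance grades used throughout the package, in fixed order.
#' @export
SEED_GRADES <- c("good", "moderate", "unhealthy")

#' SeedImage: an RGB kernel image with an optional grade label
#'
#' The raw input of the grading pipeline: an `H x W x 3` array of intensities
#' in `[0, 1]`, an identifier, and optionally one of the three appearance
#' grades (`good`, `moderate`, `unhealthy`).
#'
#' @slot pixels numeric `H x W x 3` array with values in `[0, 1]`.
#' @slot label character; one of the grades, or `NA` when unlabeled.
#' @slot id character identifier.
#' @export
setClass("SeedImage",
  representation(pixels = "array", label = "character", id = "character"),
  prototype(label = NA_character_, id = ""))

setValidity("SeedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 32L || d[2] < 32L)
    return("image must be at least 32 x 32 pixels")
  if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 1)
    return("intensities must lie in [0, 1]")
  if (!is.na(object@label) && !object@label %in% SEED_GRADES)
    return(paste("label must be one of:", paste(SEED_GRADES, collapse = ", ")))
  TRUE
})

#' Construct a SeedImage
#'
#' @param pixels `H x W x 3` numeric array, intensities in `[0, 1]`.
#' @param label optional grade (`good`, `moderate`, `unhealthy`).
#' @param id identifier string.
#' @return A [SeedImage-class] object.
#' @export
SeedImage <- function(pixels, label = NA_character_, id = "") {
  new("SeedImage", pixels = pixels, label = as.character(label), id = id)
}

#' VisualDictionary: k-means visual words for one modality
#'
#' Cluster centres fit on local features of one modality; each centre is one
#' visual word of the bag-of-features vocabulary (5-dimensional colour-patch
#' features or 64-dimensional SURF descriptors).
#'
#' @slot modality `"color"` or `"surf"`.
#' @slot words `k x d` matrix of cluster centres.
#' @slot seed integer seed the dictionary was built with.
#' @export
setClass("VisualDictionary",
  representation(modality = "character", words = "matrix", seed = "integer"))

setValidity("VisualDictionary", function(object) {
  if (!object@modality %in% c("color", "surf"))
    return("modality must be 'color' or 'surf'")
  if (nrow(object@words) < 2L) return("a dictionary needs k >= 2 words")
  d <- ncol(object@words)
  if (object@modality == "color" && d != 5L)
    return("color words must be 5-dimensional")
  if (object@modality == "surf" && d != 64L)
    return("surf words must be 64-dimensional")
  if (anyDuplicated(object@words)) return("dictionary contains duplicate words")
  TRUE
})

#' DecompositionResult: low-rank + sparse split of a descriptor matrix
#'
#' Solution of `min ||X||_* + lambda ||E||_1 s.t. Y = X + E` (robust PCA) on
#' a `d x n` descriptor matrix with columns as samples.
#'
#' @slot X low-rank component (`d x n`).
#' @slot E sparse error component (`d x n`).
#' @slot lambda regularisation weight on the sparse part.
#' @slot iterations outer iterations used.
#' @slot residual relative constraint residual `||Y-X-E||_F / ||Y||_F`.
#' @slot converged logical; `FALSE` when `max_iter` was hit first.
#' @export
setClass("DecompositionResult",
  representation(X = "matrix", E = "matrix", lambda = "numeric",
                 iterations = "integer", residual = "numeric",
                 converged = "logical"))

setValidity("DecompositionResult", function(object) {
  if (!identical(dim(object@X), dim(object@E)))
    return("X and E must have identical dimensions")
  if (object@lambda <= 0) return("lambda must be positive")
  TRUE
})

#' LowRankModel: orthonormal basis spanning the denoised descriptor space
#'
#' The leading left singular vectors of a converged low-rank component,
#' retaining the smallest rank that captures at least `energy` of the squared
#' singular-value mass; used to project train and test descriptors alike.
#'
#' @slot basis `d x r` orthonormal matrix.
#' @slot rank retained rank `r`.
#' @slot singularValues all singular values of the decomposed matrix.
#' @slot energy squared-singular-value energy threshold used.
#' @export
setClass("LowRankModel",
  representation(basis = "matrix", rank = "integer",
                 singularValues = "numeric", energy = "numeric"))

setValidity("LowRankModel", function(object) {
  if (object@rank < 1L) return("rank must be >= 1")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(ncol(object@basis)))) > 1e-9)
    return("basis columns must be orthonormal")
  TRUE
})

#' ConfusionMatrix: 3 x 3 grade counts, rows = predicted, columns = actual
#'
#' Count table in the convention used throughout this package: entry `[i, j]`
#' counts samples predicted as class `i` whose actual class is `j`. Note many
#' toolkits transpose this; [confusionMatrix()] and the accessors here keep
#' rows-as-predictions consistently.
#'
#' @slot counts 3 x 3 integer matrix with grade dimnames.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  cts <- object@counts
  if (!identical(dim(cts), c(3L, 3L))) return("counts must be 3 x 3")
  if (any(cts < 0) || any(cts != round(cts))) return("counts must be non-negative integers")
  if (!identical(rownames(cts), SEED_GRADES) || !identical(colnames(cts), SEED_GRADES))
    return("dimnames must be the three grades in canonical order")
  TRUE
})

#' GradingModel: the fitted end-to-end JMBoF pipeline
#'
#' Everything needed to grade a new image: the two visual dictionaries, the
#' low-rank projection basis, feature standardisation parameters, and the
#' fitted multiclass SVM.
#'
#' @slot colorDictionary,surfDictionary [VisualDictionary-class] objects.
#' @slot lowRank [LowRankModel-class] (or `NULL`-like empty list when LRR is
#'   disabled, as in the single-modality baselines).
#' @slot scalerCenter,scalerScale per-dimension standardisation parameters.
#' @slot svm fitted `e1071::svm` object.
#' @slot classes class order used by the SVM.
#' @slot config list of pipeline settings the model was fit with.
#' @export
setClass("GradingModel",
  representation(colorDictionary = "ANY", surfDictionary = "ANY",
                 lowRank = "ANY", scalerCenter = "numeric",
                 scalerScale = "numeric", svm = "ANY",
                 classes = "character", config = "list"))

setMethod("show", "SeedImage", function(object) {
  d <- dim(object@pixels)
  cat("SeedImage", if (nzchar(object@id)) sQuote(object@id) else "",
      sprintf("%d x %d", d[1], d[2]),
      if (!is.na(object@label)) paste0("grade=", object@label) else "unlabeled",
      "\n")
})

setMethod("show", "VisualDictionary", function(object) {
  cat(sprintf("VisualDictionary modality=%s k=%d d=%d seed=%d\n",
              object@modality, nrow(object@words), ncol(object@words),
              object@seed))
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf(paste0("DecompositionResult %d x %d lambda=%.4g ",
                     "iterations=%d residual=%.3g converged=%s\n"),
              nrow(object@X), ncol(object@X), object@lambda,
              object@iterations, object@residual, object@converged))
})

setMethod("show", "LowRankModel", function(object) {
  cat(sprintf("LowRankModel rank=%d of d=%d (energy >= %.3g)\n",
              object@rank, nrow(object@basis), object@energy))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = predicted, columns = actual)\n")
  print(object@counts)
})

setMethod("show", "GradingModel", function(object) {
  cat("GradingModel:", paste(object@classes, collapse = "/"), "\n")
  if (is(object@colorDictionary, "VisualDictionary")) show(object@colorDictionary)
  if (is(object@surfDictionary, "VisualDictionary")) show(object@surfDictionary)
  if (is(object@lowRank, "LowRankModel")) show(object@lowRank)
})

#' @describeIn VisualDictionary-class matrix of visual words (k x d).
#' @param object a `VisualDictionary`.
#' @export
words <- function(object) object@words

#' @describeIn VisualDictionary-class modality tag of a dictionary.
#' @export
modality <- function(object) object@modality

#' @describeIn DecompositionResult-class low-rank component accessor.
#' @param x a `DecompositionResult`.
#' @export
lowRankPart <- function(x) x@X

#' @describeIn DecompositionResult-class sparse component accessor.
#' @export
sparsePart <- function(x) x@E

#' @describeIn ConfusionMatrix-class raw 3 x 3 count matrix accessor.
#' @export
counts <- function(x) x@counts

#' @describeIn SeedImage-class pixel array accessor.
#' @export
pixels <- function(x) x@pixels

#' @describeIn SeedImage-class grade label accessor.
#' @export
gradeLabel <- function(x) x@label
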