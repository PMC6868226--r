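# Squared Euclidean distances between rows of a and rows of b (n x m matrix).
pairwiseSq <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre. Runs under the caller's RNG.
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- pairwiseSq(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in 2L:k) {
    if (sum(d2) <= 0) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, pairwiseSq(x, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

#' Build a visual dictionary by k-means clustering
#'
#' Clusters local features of one modality into `k` visual words with
#' Lloyd's algorithm under k-means++ seeding. Iterates until the maximum
#' centre shift falls below `1e-6` or 300 iterations; clusters that empty
#' out are re-seeded to the point farthest from its assigned centre. The
#' result is bit-reproducible for a fixed seed.
#'
#' @param features `n x d` matrix of local features (d = 5 for colour
#'   patches, 64 for SURF descriptors).
#' @param k dictionary size (number of visual words; default 800).
#' @param seed integer RNG seed.
#' @param modality `"color"` or `"surf"`; inferred from `d` when missing.
#' @return A [VisualDictionary-class].
#' @export
buildDictionary <- function(features, k = 800L, seed = 1L, modality = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2L) stop("k must be >= 2")
  if (n < k)
    stop("need at least k = ", k, " features but got ", n,
         "; lower k or supply more images")
  if (is.null(modality))
    modality <- if (ncol(features) == 64L) "surf" else "color"
  wcss <- numeric(0)
  centers <- withSeed(seed, {
    ctr <- kmeansPlusPlusInit(features, k)
    for (iter in seq_len(300L)) {
      d2 <- pairwiseSq(features, ctr)
      assign <- max.col(-d2, ties.method = "first")
      wcss[iter] <- sum(d2[cbind(seq_len(n), assign)])
      newCtr <- ctr
      for (j in seq_len(k)) {
        sel <- assign == j
        if (any(sel)) newCtr[j, ] <- colMeans(features[sel, , drop = FALSE])
        else {
          # re-seed an empty cluster at the worst-represented point
          far <- which.max(d2[cbind(seq_len(n), assign)])
          newCtr[j, ] <- features[far, ]
          assign[far] <- j
        }
      }
      shift <- max(abs(newCtr - ctr))
      ctr <- newCtr
      if (shift < 1e-6) break
    }
    ctr
  })
  out <- new("VisualDictionary", modality = modality, words = centers,
             seed = as.integer(seed))
  attr(out, "wcss") <- wcss   # within-cluster sum of squares per iteration
  out
}

#' Encode local features as a visual-word histogram
#'
#' Assigns every feature to its nearest (Euclidean) visual word and returns
#' the L1-normalised count histogram. An image with no features encodes as
#' the all-zero histogram (with a warning), so feature-free images remain
#' representable.
#'
#' @param features `n x d` matrix (or NULL / zero rows).
#' @param dictionary a [VisualDictionary-class].
#' @return Numeric vector of length `k` summing to 1 (or all zeros), with a
#'   `modality` attribute.
#' @export
encodeHistogram <- function(features, dictionary) {
  k <- nrow(words(dictionary))
  if (is.null(features) || nrow(as.matrix(features)) == 0L) {
    warning("no features to encode; returning a zero histogram")
    h <- numeric(k)
  } else {
    features <- as.matrix(features)
    if (ncol(features) != ncol(words(dictionary)))
      stop("feature dimension ", ncol(features), " does not match dictionary (",
           ncol(words(dictionary)), ")")
    assign <- max.col(-pairwiseSq(features, words(dictionary)),
                      ties.method = "first")
    h <- tabulate(assign, nbins = k)
    h <- h / sum(h)
  }
  attr(h, "modality") <- modality(dictionary)
  h
}

#' Concatenate per-modality histograms into a joint descriptor
#'
#' Fixed order: colour first, then SURF, whatever order the histograms were
#' computed in. Either half may be all-zero.
#'
#' @param colorHist histogram with modality `"color"`.
#' @param surfHist histogram with modality `"surf"`.
#' @return Numeric vector of length `k_color + k_surf`.
#' @export
joinDescriptors <- function(colorHist, surfHist) {
  if (!identical(attr(colorHist, "modality"), "color"))
    stop("first argument must be a color histogram")
  if (!identical(attr(surfHist, "modality"), "surf"))
    stop("second argument must be a surf histogram")
  out <- c(as.numeric(colorHist), as.numeric(surfHist))
  attr(out, "kColor") <- length(colorHist)
  attr(out, "kSurf") <- length(surfHist)
  out
}
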