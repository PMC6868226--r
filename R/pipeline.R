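#' Read a seed-kernel image from disk
#'
#' PNG is read with the png package; other formats (JPEG) are read through
#' EBImage when it is installed. Pixels are scaled to `[0, 1]`; an alpha
#' channel is dropped and grayscale is replicated to three channels.
#'
#' @param path image file path.
#' @param label optional grade label.
#' @param id identifier (defaults to the file name without extension).
#' @return A [SeedImage-class].
#' @export
readSeedImage <- function(path, label = NA_character_,
                          id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    px <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(px)) >= 2L) px <- aperm(px, c(2L, 1L, seq_along(dim(px))[-(1:2)]))
  } else {
    stop("only PNG is supported without EBImage installed: ", path)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  SeedImage(clamp(px), label = label, id = id)
}

#' Read a labeled dataset directory
#'
#' Expects one subdirectory per grade label containing the images of that
#' grade (the layout written by [generateDataset()]).
#'
#' @param dir dataset root directory.
#' @return List of labeled [SeedImage-class] objects.
#' @export
readSeedDataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[basename(subs) %in% SEED_GRADES]
  if (length(subs) == 0L)
    stop("no grade subdirectories (good/moderate/unhealthy) under ", dir)
  imgs <- list()
  for (s in subs) {
    files <- list.files(s, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in sort(files))
      imgs[[length(imgs) + 1L]] <- readSeedImage(f, label = basename(s))
  }
  imgs
}

#' Pipeline configuration
#'
#' Settings of the end-to-end grading pipeline. Dictionary sizes default to
#' 64 words per modality — the desk-scale setting used throughout the
#' package's own experiments; [buildDictionary()] itself defaults to the
#' full-scale 800.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param kColor,kSurf visual-dictionary sizes per modality.
#' @param tile colour-patch tile side in pixels.
#' @param surfThreshold,maxPoints SURF detection settings.
#' @param lambda robust-PCA sparse weight (`NULL` = `1/sqrt(max(d, n))`).
#' @param energy low-rank basis energy threshold.
#' @param trainFraction stratified split fraction.
#' @param transductive decompose train+test jointly instead of projecting
#'   test descriptors onto the training basis.
#' @param baselines single-modality baselines to run (subset of
#'   `"rgb"`, `"hsi"`, `"lab"`, `"surf"`; `character(0)` to skip).
#' @param costGrid,cvFolds SVM model-selection settings.
#' @param maxDictFeatures cap on pooled features fed to k-means.
#' @return List of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, kColor = 64L, kSurf = 64L, tile = 16L,
                           surfThreshold = 4e-4, maxPoints = 200L,
                           lambda = NULL, energy = 1.0,
                           trainFraction = 0.7, transductive = FALSE,
                           baselines = c("rgb", "hsi", "lab", "surf"),
                           costGrid = c(0.1, 1, 10, 100), cvFolds = 5L,
                           maxDictFeatures = 20000L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

poolFeatures <- function(featList, maxN, seed) {
  pooled <- do.call(rbind, featList)
  if (nrow(pooled) > maxN) {
    keep <- withSeed(seed, sample.int(nrow(pooled), maxN))
    pooled <- pooled[sort(keep), , drop = FALSE]
  }
  pooled
}

# Encode a list of per-image feature matrices into a k x n histogram matrix.
encodeAll <- function(featList, dictionary) {
  out <- vapply(featList, function(f) {
    as.numeric(suppressWarnings(encodeHistogram(f, dictionary)))
  }, numeric(nrow(words(dictionary))))
  matrix(out, nrow = nrow(words(dictionary)))
}

fitEvalSvm <- function(trainX, trainY, testX, testY, config, stage) {
  model <- trainClassifier(trainX, trainY, costGrid = config$costGrid,
                           cvFolds = config$cvFolds,
                           seed = deriveSeed(config$seed, stage))
  prTrain <- predictGrades(model, trainX)
  prTest <- predictGrades(model, testX)
  list(model = model,
       train = evaluatePredictions(prTrain$labels, trainY, prTrain$scores),
       test = evaluatePredictions(prTest$labels, testY, prTest$scores))
}

#' Run the full JMBoF grading pipeline
#'
#' Executes the six pipeline stages in order on a labeled image set:
#' colour-patch extraction, SURF extraction, per-modality dictionary
#' building (on training images only), histogram encoding and
#' concatenation, low-rank + sparse denoising with basis projection, and
#' multiclass SVM training — then evaluates on the held-out stratified
#' split and runs any configured single-modality baselines on the same
#' split.
#'
#' @param data a dataset directory (see [readSeedDataset()]), a list of
#'   labeled [SeedImage-class] objects, or a [synthConfig()] (a synthetic
#'   dataset of `synthCounts` images per grade is generated).
#' @param config a [pipelineConfig()].
#' @param synthCounts per-grade counts when `data` is a `synthConfig`.
#' @return List of class `"jmbofRun"`: `model` (a [GradingModel-class]),
#'   `reports` (per method: `train` and `test` `"jmbofReport"`s), `split`,
#'   and `manifest` (stage timings, seeds, dimensions, LRR rank/residual).
#' @export
runPipeline <- function(data, config = pipelineConfig(), synthCounts = 60L) {
  t0 <- Sys.time()
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t, units = "secs"))
  }

  t <- tic()
  if (inherits(data, "synthConfig")) {
    data <- generateSeedImages(synthCounts, data,
                               seed = deriveSeed(config$seed, "synth"))
  } else if (is.character(data)) {
    data <- readSeedDataset(data)
  }
  labels <- vapply(data, gradeLabel, character(1))
  if (anyNA(labels)) stop("stage load: all images must carry a grade label")
  ids <- vapply(data, function(x) x@id, character(1))
  toc(t, "load")

  split <- stratifiedSplit(labels, config$trainFraction,
                           deriveSeed(config$seed, "split"))
  tr <- split$train; te <- split$test

  t <- tic()
  labFeats <- lapply(data, colorFeatures, colorspace = "lab",
                     tile = config$tile)
  toc(t, "color_features")

  t <- tic()
  surfFeats <- lapply(data, function(im) {
    extractSurfFeatures(im, threshold = config$surfThreshold,
                        maxPoints = config$maxPoints)$descriptors
  })
  toc(t, "surf_features")

  t <- tic()
  colorDict <- buildDictionary(
    poolFeatures(labFeats[tr], config$maxDictFeatures,
                 deriveSeed(config$seed, "poolc")),
    k = config$kColor, seed = deriveSeed(config$seed, "dictc"),
    modality = "color")
  surfDict <- buildDictionary(
    poolFeatures(surfFeats[tr], config$maxDictFeatures,
                 deriveSeed(config$seed, "pools")),
    k = config$kSurf, seed = deriveSeed(config$seed, "dicts"),
    modality = "surf")
  toc(t, "dictionaries")

  t <- tic()
  D <- rbind(encodeAll(labFeats, colorDict), encodeAll(surfFeats, surfDict))
  toc(t, "encode")

  t <- tic()
  decompCols <- if (config$transductive) seq_along(data) else tr
  dec <- rpcaDecompose(D[, decompCols, drop = FALSE], lambda = config$lambda)
  basis <- fitLowRankBasis(dec, energy = config$energy)
  proj <- projectDescriptors(basis, D)
  toc(t, "lowrank")

  t <- tic()
  jm <- fitEvalSvm(t(proj[, tr, drop = FALSE]), labels[tr],
                   t(proj[, te, drop = FALSE]), labels[te], config, "svm")
  toc(t, "svm")

  reports <- list(jmbof = list(train = jm$train, test = jm$test))

  t <- tic()
  for (bl in config$baselines) {
    feats <- switch(bl,
      rgb = lapply(data, colorFeatures, colorspace = "rgb", tile = config$tile),
      hsi = lapply(data, colorFeatures, colorspace = "hsi", tile = config$tile),
      lab = labFeats,
      surf = surfFeats,
      stop("unknown baseline: ", bl))
    kB <- if (bl == "surf") config$kSurf else config$kColor
    dict <- if (bl == "lab") colorDict
            else if (bl == "surf") surfDict
            else buildDictionary(
              poolFeatures(feats[tr], config$maxDictFeatures,
                           deriveSeed(config$seed, paste0("pool", bl))),
              k = kB, seed = deriveSeed(config$seed, paste0("dict", bl)),
              modality = if (bl == "surf") "surf" else "color")
    H <- encodeAll(feats, dict)
    fit <- fitEvalSvm(t(H[, tr, drop = FALSE]), labels[tr],
                      t(H[, te, drop = FALSE]), labels[te], config,
                      paste0("svm", bl))
    reports[[bl]] <- list(train = fit$train, test = fit$test)
  }
  toc(t, "baselines")

  model <- new("GradingModel", colorDictionary = colorDict,
               surfDictionary = surfDict, lowRank = basis,
               scalerCenter = jm$model$scaler$center,
               scalerScale = jm$model$scaler$scale,
               svm = jm$model, classes = jm$model$classes,
               config = unclass(config))

  manifest <- list(
    seed = config$seed,
    nImages = length(data), nTrain = length(tr), nTest = length(te),
    kColor = config$kColor, kSurf = config$kSurf,
    jointDimension = nrow(D),
    lrrRank = basis@rank, lrrResidual = dec@residual,
    lrrIterations = dec@iterations, lambda = dec@lambda,
    svmCost = jm$model$cost, svmGamma = jm$model$gamma,
    timings = as.list(timings),
    totalSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(model = model, reports = reports, split = split,
                 ids = ids, labels = labels, manifest = manifest),
            class = "jmbofRun")
}

#' @export
print.jmbofRun <- function(x, ...) {
  cat("JMBoF pipeline run:", x$manifest$nImages, "images (",
      x$manifest$nTrain, "train /", x$manifest$nTest, "test ), LRR rank",
      x$manifest$lrrRank, "\n")
  for (m in names(x$reports)) {
    cat(sprintf("  %-6s train %.1f%%  test %.1f%%  test mAP %.3f\n", m,
                x$reports[[m]]$train$accuracy, x$reports[[m]]$test$accuracy,
                x$reports[[m]]$test$mAP))
  }
  invisible(x)
}

#' Grade new images with a fitted model
#'
#' Runs feature extraction, histogram encoding, low-rank projection and SVM
#' prediction with the parameters frozen in the model.
#'
#' @param model a [GradingModel-class] from [runPipeline()].
#' @param images a list of [SeedImage-class] objects (or a single one).
#' @return List with `labels` and `scores` as in [predictGrades()].
#' @export
gradeImages <- function(model, images) {
  if (is(images, "SeedImage")) images <- list(images)
  cfg <- model@config
  labFeats <- lapply(images, colorFeatures, colorspace = "lab",
                     tile = cfg$tile)
  surfFeats <- lapply(images, function(im) {
    extractSurfFeatures(im, threshold = cfg$surfThreshold,
                        maxPoints = cfg$maxPoints)$descriptors
  })
  D <- rbind(encodeAll(labFeats, model@colorDictionary),
             encodeAll(surfFeats, model@surfDictionary))
  proj <- projectDescriptors(model@lowRank, D)
  predictGrades(model@svm, t(proj))
}

MODEL_FORMAT_VERSION <- 1L

#' Persist / restore a fitted grading model
#'
#' The saved file round-trips the dictionaries, low-rank basis, scaler and
#' SVM: a reloaded model predicts identically. Files carry a format version
#' and are rejected with a clean error on mismatch or corruption.
#'
#' @param model a [GradingModel-class].
#' @param path file path (conventionally `.rds`).
#' @return `saveModel`: the path, invisibly. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  if (!is(model, "GradingModel")) stop("model must be a GradingModel")
  saveRDS(list(format = "jmbof-model", version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("cannot read model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "jmbof-model"))
    stop("not a jmbof model file: ", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("model format version ", obj$version, " is not supported")
  obj$model
}
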