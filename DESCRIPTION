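Package: jmbof
Title: Jointly Multi-Modal Bag-of-Features Grading of Seed Kernel Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Grades seed-kernel images into good, moderate and unhealthy
    appearance classes with a jointly multi-modal bag-of-features (JMBoF)
    pipeline: spatial CIE L*a*b* colour-patch features and SURF local
    descriptors are quantised against per-modality k-means visual
    dictionaries, the concatenated word histograms are denoised by a
    low-rank plus sparse (robust PCA) decomposition, and the reduced
    representation is classified with a multiclass support vector machine.
    Includes single-modality baselines (RGB/HSI/L*a*b*/SURF bag-of-features),
    confusion-matrix / precision-recall / mAP evaluation, and a synthetic
    seed-image generator with grade-dependent defects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    png,
    jsonlite
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
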