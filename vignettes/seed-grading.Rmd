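---
title: "Grading seed kernels with jointly multi-modal bags of features"
author: "jmbof authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading seed kernels with jointly multi-modal bags of features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmbof)
```

## The problem

Postharvest dry seed quality is routinely judged by appearance: an intact,
smooth seed coat and plump cotyledons mark a good kernel; a broken coat or
cracked cotyledon a moderate one; severe shrivelling, mould, worm bites,
decay or deformation an unhealthy one. Screening large lots by eye is slow,
so machine-vision grading from flatbed-scanner images of individual kernels
is attractive. Global colour or shape statistics struggle here because the
deciding evidence is often a small local structure — a hairline crack, one
mould spot — that global averages wash out. This package implements a
local-feature pipeline: two bags of quantised local features (colour
patches and SURF descriptors), fused and denoised by a low-rank + sparse
decomposition, classified by a multiclass SVM, with single-modality
baselines and full evaluation alongside.

## The model, stage by stage

### Colour features

RGB in `[0, 1]` is mapped linearly to CIE XYZ with the fixed matrix whose
rows are `(0.4124, 0.3576, 0.1805)`, `(0.2126, 0.7152, 0.0722)` and
`(0.0193, 0.1192, 0.9505)`, then to L\*a\*b\* relative to a reference
white. Two conventions needed deciding:

* **Reference white.** None is specified by the transform itself; we use
  the image of RGB white under the package's own matrix,
  `(0.9505, 1.0000, 1.0890)`, so that white maps exactly to `L* = 100` and
  neutral greys to `a* = b* = 0`.
* **Gamma.** The matrix is applied to the raw intensities, with an optional
  `linearize` flag for sRGB-decoded input. Applied to raw values the map is
  exactly linear, which the tests exploit; for grading, what matters is a
  consistent, discriminative embedding rather than colourimetric truth.

The piecewise `f(t)` uses the knee `0.0089` and linear branch
`7.7870 t + 0.1379` verbatim, although they are printed at lower precision
than the CIE constants (`0.008856`, `7.787`, `16/116`); the two branches
still agree to `3.1e-5` at the knee, so the transform is effectively
continuous. Each non-overlapping 16×16-**pixel** tile (not a 16×16 grid —
so the feature count scales with image area) contributes its three channel
means plus the tile centre normalised by image width and height. The
normalised coordinates make the spatial layout scale-invariant; note that
against L\*a\*b\* channel ranges (~100) the `[0, 1]` coordinates carry
little weight in Euclidean clustering — they matter more for the RGB and
HSI baselines, whose channels share the coordinates' scale.

### SURF

The detector is the classical box-filter approximation of the Hessian
determinant on an integral image: 3 octaves × 4 levels starting from the
9×9 filter, sampling stride doubling per octave, mixed-derivative weight
0.9, strict 3×3×3 non-maximum suppression **without** sub-pixel
interpolation (omitted for determinism). Each point carries the sign of
`Dxx + Dyy`: `+1` flags dark-on-bright blobs (cracks, mould), `-1` the
reverse. The default determinant threshold `4e-4` (intensities in
`[0, 1]`) yields tens of points on a defective 128 px kernel.

The descriptor follows the 12×12 variant: Haar responses (window
`2*scale`) at 12×12 regularly spaced samples across an oriented window of
side `20*scale`, i.e. 3×3 samples in each of the 4×4 subregions, weighted
by a Gaussian with `sigma = 3.3*scale`, summed per subregion into
`(Σdx, Σdy, Σ|dx|, Σ|dy|)` and L2-normalised — 64 dimensions. Canonical
SURF samples 5×5 per subregion; the 12×12 grid is the implemented variant
and the descriptor remains rotation-robust (quarter-turn cosine similarity
above 0.8 in the tests). Orientation uses Haar responses on a radius-6
scale-normalised circular grid, Gaussian weight `sigma = 2.5*scale`, and a
sliding 60° window scanned in fixed 0.15 rad steps; ties keep the first
maximal window, making the assignment deterministic.

Border handling: rectangle sums are clipped to the image by the integral
image, so Haar windows overhanging the border contribute their in-bounds
part. Points are skipped only when the orientation sampling ring
(`6*scale`) does not fit. Skipping instead every point whose rotated
descriptor window leaves the image would discard all outline points of a
kernel filling a 128 px frame and leave defect-free kernels featureless.
Images with no features at all encode as the zero histogram (with a
warning), keeping them representable.

### Bag of features

Per modality, k-means (Lloyd) with k-means++ seeding under an explicit
seed, convergence when the largest centre shift drops below `1e-6` or
after 300 iterations, and empty clusters re-seeded to the farthest point.
This is hand-written rather than delegated because the contract —
seeded k-means++, the re-seeding rule, bitwise reproducibility — is not
reachable through `stats::kmeans` options; `stats::kmeans` instead serves
as an independent cross-check in the tests. Dictionaries hold 800 words
per modality at full scale (so the joint descriptor has 1600 entries);
the package's own experiments use 64 per modality, matched to desk-scale
feature counts (see below). Histograms are L1-normalised so images with
different feature counts (SURF counts vary a lot) remain comparable, and
dictionaries are fit on **training** features only to avoid leakage.

### Low-rank + sparse fusion

The concatenated histogram matrix `Y` (rows = joint-descriptor entries,
columns = images) is split by `min ||X||_* + lambda ||E||_1` subject to
`Y = X + E`, the robust-PCA objective, with the standard
`lambda = 1/sqrt(max(d, n))`. The solver is inexact ALM:
`mu0 = 1.25 / ||Y||_2`, growth `rho = 1.5`, singular-value thresholding
for `X`, soft thresholding for `E`, dual update, stopping at relative
residual `1e-7` (cap 500 iterations, non-convergence returns a flagged
result with a warning). Two numerical notes:

* The recorded objective is **not** monotone: starting from `X = E = 0`
  the iterates are infeasible and the objective rises toward its limit,
  then oscillates at `~1e-7` relative as `mu` saturates. The tests
  therefore check objective convergence and optimality against the
  trivial feasible splits `(Y, 0)` and `(0, Y)`, plus exact recovery of
  planted low-rank + sparse matrices.
* How unseen images get a representation is undefined in the
  transductive formulation, so the default is inductive: decompose the
  training matrix, keep the orthonormal basis of `X`, and project train
  and test alike. A `transductive` flag decomposes train+test jointly for
  comparison.

`fitLowRankBasis` keeps the smallest rank capturing 99% of squared
singular-value energy by default, which suits planted-rank recovery. The
pipeline, however, passes `energy = 1.0` (full numerical rank of `X`): on
word histograms the spectrum is dominated by the mean histogram, and a
0.99 cut keeps rank ~3 of ~80, collapsing the three classes (measured:
49% training accuracy versus 100% at full rank). The denoising then comes
from removing `E` and the exactly-zero trailing singular values that
nuclear-norm shrinkage produces, not from an additional energy cut.

### Classification and evaluation

Features are z-scored with training statistics (constant dimensions pass
through). The SVM is RBF-kernel, one-vs-one (libsvm via e1071), with
`C ∈ {0.1, 1, 10, 100}` and kernel width `2^{-4..2}/p` selected by
stratified 5-fold cross-validation by default; leave-one-out (`k = n`,
each sample validated once by a model fit on the rest) is available via
`cvFolds = "loo"` and in `crossValidate()`, but is opt-in since `n` SVM
fits per grid point is slow at realistic `n`. Model selection never sees
the held-out split. Per-class scores for PR curves come from vote-margin
aggregation of the pairwise decision values.

The confusion matrix convention is rows = predicted, columns = actual —
the transpose of several toolkits — and all derived percentages follow it;
percentages compared against printed values round half-up to one decimal.
Average precision is the step-wise (non-interpolated) area under the
one-vs-rest precision–recall curve, swept over every distinct score with
tied scores grouped; mAP is the unweighted three-class mean. The
stratified split sends `round(0.7 * n_c)` of each class to training —
with 281 per class, exactly 197/84, reproducing the canonical 591/252
partition.

## The synthetic generator

Real graded kernel photographs are not shipped, so `generateSeedImage`
draws them: an anti-aliased ellipse (semi-axes ~42×30 px jittered, random
orientation) with a pale-yellow coat, quadratic radial shading, mild
speckle (`sd = 0.012`) and slight per-image colour jitter (±0.02), on a
near-black background emulating a scanner's black absorption cover — which
concentrates SURF points on the kernel outline, as on real scans. Grade
semantics:

* **good** — no defects; by construction no fully-covered kernel pixel
  falls below 0.35 luminance.
* **moderate** — 1–3 thin dark cracks (random walks steered back onto the
  kernel, 3 px wide, ×0.30 darkening) or, with probability 0.4, a pale
  exposed-cotyledon patch bounded by a dark torn-coat rim.
* **unhealthy** — two or three of: sinusoidal shrivel ridges (amplitude
  0.20, ~6 px period), 3–5 dark mould blobs, a bite notch on the outline,
  strong low-frequency outline deformation; plus, half the time, a
  structureless decayed-testa tint (coat multiplied by ~0.5–0.75 per
  channel).

Severities were chosen once so that each modality is informative but
incomplete: shrivel ridges average out of 16 px tile means
(gradient-visible, colour-blind), while the decay tint is smooth
(colour-visible, gradient-blind). Single-modality baselines therefore
succeed moderately, with the joint model on top at the package's default
configuration — mirroring the expected model ordering. SURF alone runs a
close second (the structural defects suffice for most kernels), so at 54
test images its gap to the joint model is one or two kernels and can close
under other random draws; the colour baselines trail by a wide, stable
margin. Every image records the defects actually drawn (`defects`
attribute) and its kernel mask, and generation is bit-reproducible from
`(config, seed)` with per-image derived seeds.

What the generator does **not** emulate: real seed-coat texture and gloss,
specular highlights, inter-cultivar colour variation, soil/debris,
touching kernels, scanner optics. Passing the end-to-end tests shows the
pipeline separates the generator's defect taxonomy at these severities; it
does not certify accuracy on real lots.

## Problem sizes and runtimes

The package's experiments use 60 images per grade at 128×128, 64 words
per modality, and the default 70/30 split — about half a minute end to end
including the four baselines. Unit tests run exhaustive oracles at tiny
sizes (8×8 integral images, 2-means on four points, planted 120–200²
robust-PCA instances). Full-scale settings (800 words, hundreds of images)
are a matter of configuration, not code.

## Known limitations

* Pure-R SURF is O(0.1 s) per 128 px image; large scans or thousands of
  images would motivate a compiled detector.
* The RBF-SVM grid is coarse by design; per-dataset tuning may help.
* The low-rank step helps most when histograms are long and redundant
  (large k); with k = 64 per modality its margin over raw concatenation
  is modest.
* HSI hue is returned on `[0, 1)` with `H = 0` for achromatic pixels, a
  convention that can place near-grey pixels far apart in hue.
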