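#' Configuration of the synthetic seed-image generator
#'
#' Parameters of the synthetic kernels: an anti-aliased ellipse with smooth
#' radial shading and mild speckle on a near-black background (emulating a
#' scanner's black absorption cover), plus grade-dependent defects.
#' Moderate kernels get 1-2 thin dark crack curves or a pale coat-break
#' patch; unhealthy kernels get at least two of: dense shrivel ridges
#' (sinusoidal luminance modulation), dark mold blobs, a bite notch on the
#' outline, or strong shape deformation.
#'
#' @param imageSize image side in pixels (>= 64; default 128).
#' @param baseColor mean RGB seed-coat colour (pale soybean yellow).
#' @param colorJitter per-image uniform jitter half-width on each channel.
#' @param shading radial darkening strength toward the kernel edge.
#' @param speckleSd pixel speckle noise standard deviation.
#' @param axes mean ellipse semi-axes in pixels (scaled with `imageSize`).
#' @param axisJitter half-width of the uniform jitter on each semi-axis.
#' @param crackCount range (min, max) of crack curves on moderate kernels.
#' @param crackDarkness multiplicative darkening inside a crack.
#' @param breakProb probability a moderate kernel shows a coat-break patch
#'   instead of cracks.
#' @param shrivelAmp,shrivelFreq amplitude and spatial frequency
#'   (cycles/pixel) of the shrivel ridge modulation.
#' @param moldCount range of mold blob counts; `moldRadius` their pixel
#'   radius range; `moldColor` their RGB colour.
#' @param notchRadius range of bite-notch radii in pixels.
#' @param deformAmp outline deformation amplitude for heteromorphic shapes.
#' @return List of class `"synthConfig"`.
#' @export
synthConfig <- function(imageSize = 128L,
                        baseColor = c(0.84, 0.70, 0.32),
                        colorJitter = 0.02,
                        shading = 0.30,
                        speckleSd = 0.012,
                        axes = c(42, 30),
                        axisJitter = 4,
                        crackCount = c(1L, 3L),
                        crackDarkness = 0.30,
                        breakProb = 0.4,
                        shrivelAmp = 0.20,
                        shrivelFreq = 0.16,
                        moldCount = c(3L, 5L),
                        moldRadius = c(3, 7),
                        moldColor = c(0.26, 0.28, 0.18),
                        notchRadius = c(8, 14),
                        deformAmp = 0.22) {
  if (imageSize < 64L) stop("imageSize must be >= 64")
  cfg <- as.list(environment())
  class(cfg) <- "synthConfig"
  cfg
}

# Thin dark crack: a jittered random walk stamped into a pixel mask. The
# walk is steered back toward the kernel centre when it approaches the
# outline (`rr` is the normalised elliptical radius field), so every crack
# stays visibly on the kernel.
crackMask <- function(S, cx, cy, maxR, rr) {
  mask <- matrix(FALSE, S, S)
  ang <- runif(1, 0, 2 * pi)
  r0 <- runif(1, 0, 0.4) * maxR
  x <- cx + r0 * cos(ang); y <- cy + r0 * sin(ang)
  dir <- runif(1, 0, 2 * pi)
  len <- round(runif(1, 1.0, 1.6) * maxR)
  for (step in seq_len(len)) {
    dir <- dir + rnorm(1, 0, 0.18)
    xi <- round(x + cos(dir)); yi <- round(y + sin(dir))
    if (xi < 2 || xi > S - 1 || yi < 2 || yi > S - 1 || rr[yi, xi] > 0.85) {
      # turn back toward the centre and continue
      dir <- atan2(cy - y, cx - x) + rnorm(1, 0, 0.3)
      xi <- round(x + cos(dir)); yi <- round(y + sin(dir))
      if (xi < 2 || xi > S - 1 || yi < 2 || yi > S - 1) break
    }
    x <- x + cos(dir); y <- y + sin(dir)
    mask[yi + (-1:1), xi + (-1:1)] <- TRUE
  }
  mask
}

#' Generate one synthetic seed-kernel image
#'
#' Deterministic for a fixed `(config, seed)` pair. The defect structures
#' actually drawn are recorded in the `defects` attribute of the returned
#' object so failures stay debuggable.
#'
#' @param grade `"good"`, `"moderate"` or `"unhealthy"`.
#' @param config a [synthConfig()].
#' @param seed integer RNG seed for this image.
#' @param id identifier for the resulting [SeedImage-class].
#' @return A [SeedImage-class] with attributes `defects` (character vector
#'   of drawn defect structures) and `kernelMask` (logical matrix of fully
#'   covered kernel pixels).
#' @export
generateSeedImage <- function(grade, config = synthConfig(), seed = 1L,
                              id = paste0(grade, "_", seed)) {
  if (!grade %in% SEED_GRADES) stop("unknown grade: ", grade)
  S <- as.integer(config$imageSize)
  scl <- S / 128
  withSeed(seed, {
    defects <- character(0)
    # choose unhealthy defect set up front (deformation changes the outline)
    if (grade == "unhealthy") {
      nDef <- sample(2:3, 1)
      defects <- sample(c("shrivel", "mold", "notch", "deform"), nDef)
      # half of unhealthy kernels additionally carry a structureless
      # decayed-testa tint, visible to colour but not to local gradients
      if (runif(1) < 0.5) defects <- c(defects, "decay")
    } else if (grade == "moderate") {
      defects <- if (runif(1) < config$breakProb) "break" else "crack"
    }
    cx <- S / 2 + runif(1, -4, 4) * scl
    cy <- S / 2 + runif(1, -4, 4) * scl
    a <- (config$axes[1] + runif(1, -1, 1) * config$axisJitter) * scl
    b <- (config$axes[2] + runif(1, -1, 1) * config$axisJitter) * scl
    phi <- runif(1, 0, pi)
    X <- matrix(rep(seq_len(S), each = S), S, S)   # column index
    Y <- matrix(rep(seq_len(S), times = S), S, S)  # row index
    u <- ((X - cx) * cos(phi) + (Y - cy) * sin(phi)) / a
    v <- (-(X - cx) * sin(phi) + (Y - cy) * cos(phi)) / b
    rr <- sqrt(u^2 + v^2)
    if ("deform" %in% defects) {
      th <- atan2(v, u)
      ph2 <- runif(2, 0, 2 * pi)
      rr <- rr * (1 + config$deformAmp * (0.6 * sin(2 * th + ph2[1]) +
                                          0.4 * sin(3 * th + ph2[2])))
    }
    alpha <- clamp((1 - rr) * 14, 0, 1)            # ~2 px anti-aliased edge
    if ("notch" %in% defects) {
      bang <- runif(1, 0, 2 * pi)
      # a boundary point of the (possibly deformed) ellipse
      bx <- cx + a * cos(bang) * cos(phi) - b * sin(bang) * sin(phi)
      by <- cy + a * cos(bang) * sin(phi) + b * sin(bang) * cos(phi)
      nr <- runif(1, config$notchRadius[1], config$notchRadius[2]) * scl
      dn <- sqrt((X - bx)^2 + (Y - by)^2)
      alpha <- pmin(alpha, clamp((dn - nr) * 2, 0, 1))
    }
    coat <- clamp(config$baseColor + runif(3, -1, 1) * config$colorJitter, 0, 1)
    if ("decay" %in% defects)
      coat <- coat * c(runif(1, 0.55, 0.70), runif(1, 0.50, 0.62),
                       runif(1, 0.55, 0.75))
    shade <- 1 - config$shading * pmin(rr, 1)^2
    lumMod <- shade
    if ("shrivel" %in% defects) {
      psi <- runif(1, 0, pi)
      ph3 <- runif(1, 0, 2 * pi)
      ridges <- 1 + config$shrivelAmp *
        sin(2 * pi * config$shrivelFreq / scl * (X * cos(psi) + Y * sin(psi)) + ph3)
      lumMod <- lumMod * ridges
      defects <- unique(defects)
    }
    img <- array(0, c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- coat[ch] * lumMod
    if ("crack" %in% defects) {
      nCracks <- sample(config$crackCount[1]:config$crackCount[2], 1)
      for (i in seq_len(nCracks)) {
        cm <- crackMask(S, cx, cy, max(a, b) * 0.8, rr)
        cm <- cm & rr < 0.92
        for (ch in 1:3) img[, , ch][cm] <- img[, , ch][cm] * config$crackDarkness
      }
      defects <- c(setdiff(defects, "crack"), rep("crack", nCracks))
    }
    if ("break" %in% defects) {
      # exposed pale cotyledon patch bounded by the dark torn-coat rim
      pang <- runif(1, 0, 2 * pi); prad <- runif(1, 0.2, 0.55)
      px <- cx + prad * a * cos(pang); py <- cy + prad * b * sin(pang)
      pr <- runif(1, 7, 12) * scl
      dp <- sqrt((X - px)^2 + (Y - py)^2)
      pa <- clamp(1.2 * exp(-dp^2 / (2 * pr^2)), 0, 1)
      rim <- exp(-(dp - pr)^2 / (2 * 1.5^2)) * (rr < 0.9)
      pale <- c(0.97, 0.92, 0.60)
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - pa) + pale[ch] * lumMod * pa
        img[, , ch] <- img[, , ch] * (1 - 0.6 * rim)
      }
    }
    if ("mold" %in% defects) {
      nMold <- sample(config$moldCount[1]:config$moldCount[2], 1)
      for (i in seq_len(nMold)) {
        mang <- runif(1, 0, 2 * pi); mrad <- runif(1, 0, 0.7)
        mx <- cx + mrad * a * cos(mang); my <- cy + mrad * b * sin(mang)
        mr <- runif(1, config$moldRadius[1], config$moldRadius[2]) * scl
        ma <- clamp(1.4 * exp(-((X - mx)^2 + (Y - my)^2) / (2 * mr^2)), 0, 1)
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - ma) + config$moldColor[ch] * ma
      }
      defects <- c(setdiff(defects, "mold"), rep("mold", nMold))
    }
    # composite over the near-black background, then speckle
    bg <- 0.045
    for (ch in 1:3) img[, , ch] <- bg * (1 - alpha) + img[, , ch] * alpha
    img <- clamp(img + array(rnorm(S * S * 3, 0, config$speckleSd), dim(img)))
    out <- SeedImage(img, label = grade, id = id)
    attr(out, "defects") <- defects
    attr(out, "kernelMask") <- alpha >= 0.999   # fully covered kernel pixels
    out
  })
}

#' Generate a labeled set of synthetic seed images in memory
#'
#' @param counts named vector of per-grade image counts (names from
#'   `good`, `moderate`, `unhealthy`); a single unnamed number is recycled
#'   to all three grades.
#' @param config a [synthConfig()].
#' @param seed base RNG seed; image `i` of grade `g` uses a seed derived
#'   from it, so any subset is reproducible independently.
#' @return List of [SeedImage-class] objects.
#' @export
generateSeedImages <- function(counts = 60L, config = synthConfig(),
                               seed = 1L) {
  if (is.null(names(counts)))
    counts <- stats::setNames(rep(counts[1], 3L), SEED_GRADES)
  imgs <- list()
  for (g in SEED_GRADES) {
    n <- counts[[g]]
    if (is.null(n) || n < 0) stop("invalid count for grade ", g)
    for (i in seq_len(n)) {
      s <- deriveSeed(seed, paste0(g, i))
      imgs[[length(imgs) + 1L]] <-
        generateSeedImage(g, config, seed = s,
                          id = sprintf("%s_%03d", g, i))
    }
  }
  imgs
}

#' Write a synthetic dataset to disk
#'
#' One PNG per image under a subdirectory per grade, plus a `manifest.csv`
#' recording id, grade, file and the defect structures drawn.
#'
#' @param dir output directory (created if needed).
#' @inheritParams generateSeedImages
#' @return The manifest `data.frame`, invisibly.
#' @export
generateDataset <- function(dir, counts = 60L, config = synthConfig(),
                            seed = 1L) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  imgs <- generateSeedImages(counts, config, seed)
  rows <- lapply(imgs, function(im) {
    sub <- file.path(dir, gradeLabel(im))
    if (!dir.exists(sub)) dir.create(sub)
    f <- file.path(sub, paste0(im@id, ".png"))
    png::writePNG(pixels(im), f)
    data.frame(id = im@id, grade = gradeLabel(im), file = f,
               defects = paste(attr(im, "defects"), collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
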