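# Synthetic 4-class image generator.  Class identity is carried by a
# controllable mixture of low-frequency structure (a Gaussian-blurred
# elliptical blob: size, eccentricity, position) and high-frequency texture
# (an oriented band-limited grating), so each network branch can be validated
# on data whose frequency content is known by construction.

BLUR_SIGMA <- 2       # blur of the shape field; keeps its spectrum below
                      # 0.25 cycles/pixel (Gaussian attenuation ~ exp(-2 pi^2 s^2 f^2))
TEXTURE_RMS <- 0.18   # RMS amplitude of the texture field before mixing
TEXTURE_NOISE_FRAC <- 0.25  # relative weight of the band-limited noise component
SHAPE_BASE <- 0.15    # background level of the shape field; with the 0.75
SHAPE_AMP <- 0.60     # plateau this leaves headroom so additive texture and
                      # noise rarely clip (clipping would couple class
                      # identity into out-of-band spectral energy)

# integer hash for seed derivation.  Keyed only by the values (not by list
# position), with enough bit mixing that nearby inputs give unrelated seeds:
# a weak multiplicative hash leaves per-class seed sets in arithmetic
# progression, which measurably correlates the resulting RNG streams.
hashSeeds <- function(...) {
  v <- as.numeric(c(...))
  h <- 104729
  for (x in v) {
    h <- (h * 69069 + x + 13007) %% 2147483647
    h <- as.numeric(bitwXor(as.integer(h), as.integer(h %/% 65536)))
    h <- (h * 40503 + 30011) %% 2147483647
    h <- as.numeric(bitwXor(as.integer(h), as.integer(h %/% 8192)))
  }
  as.integer(h %% 2147483646 + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Render the low-frequency shape field of one sample
#'
#' Draws a filled ellipse of area `pi * blobRadius^2` (axes scaled by the
#' eccentricity so area is eccentricity-invariant), at a jittered centre and
#' random orientation, then blurs it with a Gaussian kernel so essentially
#' all spectral energy lies below 0.25 cycles/pixel.  The field runs from a
#' background level of 0.15 to a blob plateau of 0.75 (inside [0, 1]); the
#' headroom keeps later texture/noise addition out of the clipping regime,
#' which would otherwise leak class identity into other frequency bands.
#'
#' @param spec a [SyntheticClassSpec-class] object.
#' @param size image side length (at least 32).
#' @param rngSeed integer seed; the same seed reproduces the field exactly.
#' @return a `size` x `size` matrix.
#' @export
renderShapeField <- function(spec, size, rngSeed) {
  stopifnot(is(spec, "SyntheticClassSpec"), size >= 32)
  e <- spec@blobEccentricity
  stretch <- (1 - e^2)^(-1 / 4)          # semi-major = r * stretch, semi-minor = r / stretch
  envelope <- (spec@blobRadius + 3 * spec@blobRadiusSpread) * stretch +
    3 * spec@blobCenterJitter + 3 * BLUR_SIGMA
  if (envelope > size / 2)
    stop("blobRadius: a blob of radius ", spec@blobRadius,
         " (eccentricity ", e, ", jitter ", spec@blobCenterJitter,
         ") does not fit in a ", size, "x", size, " image")
  set.seed(rngSeed)
  r <- min(max(stats::rnorm(1, spec@blobRadius, spec@blobRadiusSpread),
               spec@blobRadius - 3 * spec@blobRadiusSpread),
           spec@blobRadius + 3 * spec@blobRadiusSpread)
  r <- max(r, 1)
  theta <- stats::runif(1, 0, pi)
  jit <- pmin(pmax(stats::rnorm(2, 0, spec@blobCenterJitter),
                   -3 * spec@blobCenterJitter), 3 * spec@blobCenterJitter)
  a <- r * stretch
  b <- r / stretch
  c0 <- (size + 1) / 2
  X <- matrix(seq_len(size), size, size) - (c0 + jit[1])
  Y <- matrix(seq_len(size), size, size, byrow = TRUE) - (c0 + jit[2])
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  mask <- ((u / a)^2 + (v / b)^2 <= 1) * 1.0
  blurred <- clip01(as.matrix(EBImage::gblur(mask, sigma = BLUR_SIGMA)))
  SHAPE_BASE + SHAPE_AMP * blurred
}

fftFreqGrid <- function(size) {
  f <- c(0:(size %/% 2), -((size - (size %/% 2 + 1)):1)) / size
  fx <- matrix(f, size, size)
  fy <- matrix(f, size, size, byrow = TRUE)
  sqrt(fx^2 + fy^2)
}

#' Render the high-frequency texture field of one sample
#'
#' A zero-mean oriented grating at `textureFreq` cycles/pixel plus a weaker
#' band-limited noise component (white noise band-passed around the same
#' frequency and symmetrised), normalised to a fixed RMS amplitude.  The
#' dominant discrete-Fourier peak lies within one frequency bin of
#' `textureFreq * size`.
#'
#' @inheritParams renderShapeField
#' @return a `size` x `size` matrix with mean zero.
#' @export
renderTextureField <- function(spec, size, rngSeed) {
  stopifnot(is(spec, "SyntheticClassSpec"))
  f <- spec@textureFreq
  if (f > 0.5)
    stop("textureFreq ", f, " exceeds the Nyquist limit of 0.5 cycles/pixel")
  set.seed(rngSeed)
  phase <- stats::runif(1, 0, 2 * pi)
  white <- matrix(stats::rnorm(size * size), size, size)
  rho <- fftFreqGrid(size)
  bp <- Re(stats::fft(stats::fft(white) * exp(-(rho - f)^2 / (2 * 0.04^2)),
                      inverse = TRUE)) / (size * size)
  bp <- (bp + t(bp)) / 2
  bp <- bp / max(stats::sd(bp), 1e-12)
  th <- spec@textureOrientation * pi / 180
  X <- matrix(seq_len(size) - 1, size, size)
  Y <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  g <- cos(2 * pi * f * (X * cos(th) + Y * sin(th)) + phase)
  field <- g + TEXTURE_NOISE_FRAC * bp
  field <- field - mean(field)
  field * (TEXTURE_RMS / max(stats::sd(field), 1e-12))
}

#' Compose one labelled synthetic sample
#'
#' `image = clip(shape + hfWeight * texture + gaussian noise, 0, 1)`,
#' replicated to three channels.  When `hfWeight` is zero the texture field
#' is never rendered, so the output is exactly shape plus noise.
#'
#' @inheritParams renderShapeField
#' @return a list with elements `image` (a `size` x `size` x 3 array in
#'   [0, 1]), `classId`, and `provenance` (`"synthetic"`).
#' @export
composeSample <- function(spec, size, rngSeed) {
  shape <- renderShapeField(spec, size, hashSeeds(rngSeed, 1))
  img <- shape
  if (spec@hfWeight > 0)
    img <- img + spec@hfWeight * renderTextureField(spec, size, hashSeeds(rngSeed, 2))
  if (spec@noiseSd > 0) {
    set.seed(hashSeeds(rngSeed, 3))
    img <- img + matrix(stats::rnorm(size * size, 0, spec@noiseSd), size, size)
  }
  img <- clip01(img)
  list(image = array(img, dim = c(size, size, 3)),
       classId = spec@classId, provenance = "synthetic")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nPerClass` PNG images per class under
#' `outDir/class_<id>/img_<i>.png` plus a `manifest.csv` with columns
#' `path,class_id,seed`.  Each per-sample seed is a deterministic hash of
#' `(masterSeed, classId, sampleIndex)`, so regeneration with the same master
#' seed is byte-identical and independent of the order the specs are listed
#' in.
#'
#' @param specs list of [SyntheticClassSpec-class] objects (at least 2).
#' @param nPerClass samples per class (at least 1).
#' @param size image side length.
#' @param masterSeed master seed.
#' @param outDir output directory (created if needed).
#' @return a [SyntheticDatasetManifest-class] object.
#' @export
generateDataset <- function(specs, nPerClass, size, masterSeed, outDir) {
  if (length(specs) < 2L) stop("at least 2 class specs are required")
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  rows <- list()
  for (spec in specs) {
    cdir <- file.path(outDir, sprintf("class_%d", spec@classId))
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(nPerClass)) {
      seed <- hashSeeds(masterSeed, spec@classId, i)
      s <- composeSample(spec, size, seed)
      rel <- file.path(sprintf("class_%d", spec@classId), sprintf("img_%04d.png", i))
      EBImage::writeImage(EBImage::Image(s$image, colormode = "Color"),
                          file.path(outDir, rel))
      rows[[length(rows) + 1L]] <- data.frame(path = rel, class_id = spec@classId,
                                              seed = seed)
    }
  }
  samples <- do.call(rbind, rows)
  utils::write.csv(samples, file.path(outDir, "manifest.csv"), row.names = FALSE)
  new("SyntheticDatasetManifest", dir = outDir, imageSize = as.integer(size),
      masterSeed = as.integer(masterSeed), samples = samples)
}

#' Generate a synthetic dataset in memory as a training tensor
#'
#' Same sampling scheme as [generateDataset()] (identical per-sample seeds)
#' without touching the file system.
#'
#' @inheritParams generateDataset
#' @return list with `x` (an `(N, 3, size, size)` array) and `y` (0-based
#'   integer labels).
#' @export
synthesizeTensors <- function(specs, nPerClass, size, masterSeed) {
  n <- length(specs) * nPerClass
  x <- array(0, c(n, 3L, size, size))
  y <- integer(n)
  k <- 0L
  for (spec in specs) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      s <- composeSample(spec, size, hashSeeds(masterSeed, spec@classId, i))
      x[k, , , ] <- aperm(s$image, c(3, 1, 2))
      y[k] <- s$classId
    }
  }
  list(x = x, y = y)
}

#' Default class specifications: the generator's study conditions
#'
#' Four classes whose identity is carried by shape, texture, or both:
#' \describe{
#'   \item{`"shape"`}{`hfWeight = 0`; classes differ only in blob geometry —
#'     size (radius 6, 8, 10, 12 px) and eccentricity (0.05, 0.30, 0.45,
#'     0.60) — so the signal is purely low-frequency structure.}
#'   \item{`"texture"`}{`hfWeight = 1` with identical blob parameters across
#'     classes; classes differ only in grating frequency
#'     (0.20, 0.30, 0.40, 0.48 cycles/pixel) and orientation
#'     (0, 45, 90, 135 degrees).}
#'   \item{`"mixed"`}{both signals at `hfWeight = 0.5`.}
#' }
#' All specs share radius spread 1 px, centre jitter 3 px and pixel noise
#' `noiseSd`; blob orientation is a random nuisance variable, and blob area
#' is eccentricity-invariant.
#'
#' @param signal which component carries the class identity.
#' @param noiseSd additive pixel-noise level.
#' @return list of four [SyntheticClassSpec-class] objects.
#' @export
defaultClassSpecs <- function(signal = c("mixed", "texture", "shape"),
                              noiseSd = 0.05) {
  signal <- match.arg(signal)
  radii <- c(6, 8, 10, 12)
  eccs <- c(0.05, 0.30, 0.45, 0.60)
  freqs <- c(0.20, 0.30, 0.40, 0.48)
  orients <- c(0, 45, 90, 135)
  shapeVaries <- signal %in% c("mixed", "shape")
  textureVaries <- signal %in% c("mixed", "texture")
  lapply(0:3, function(k) {
    SyntheticClassSpec(
      classId = k,
      blobRadius = if (shapeVaries) radii[k + 1] else 9,
      blobRadiusSpread = 1,
      blobEccentricity = if (shapeVaries) eccs[k + 1] else 0.3,
      blobCenterJitter = 3,
      textureFreq = if (textureVaries) freqs[k + 1] else 0.3,
      textureOrientation = if (textureVaries) orients[k + 1] else 0,
      hfWeight = switch(signal, mixed = 0.5, texture = 1, shape = 0),
      noiseSd = noiseSd)
  })
}

#' Spectral energy of an image in a radial frequency band
#'
#' Fraction (or absolute amount) of discrete-Fourier power with radial
#' frequency in `[lo, hi)` cycles/pixel, excluding the DC component.
#'
#' @param img a matrix (one channel).
#' @param lo,hi band edges in cycles/pixel.
#' @param fraction if `TRUE`, return the fraction of total non-DC power.
#' @return a scalar.
#' @export
spectralBandEnergy <- function(img, lo, hi, fraction = FALSE) {
  p <- Mod(stats::fft(img - mean(img)))^2
  rho <- fftFreqGrid(nrow(img))
  sel <- rho >= lo & rho < hi
  e <- sum(p[sel])
  if (fraction) e / sum(p) else e
}

#' Read a generated synthetic dataset back into a tensor
#'
#' @param manifest a [SyntheticDatasetManifest-class] object.
#' @return list with `x` (an `(N, 3, size, size)` array) and `y`.
#' @export
loadSyntheticDataset <- function(manifest) {
  n <- nrow(manifest@samples)
  size <- manifest@imageSize
  x <- array(0, c(n, 3L, size, size))
  for (i in seq_len(n)) {
    img <- as.array(EBImage::readImage(file.path(manifest@dir,
                                                 manifest@samples$path[i])))
    if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
    x[i, , , ] <- aperm(img, c(3, 1, 2))
  }
  list(x = x, y = as.integer(manifest@samples$class_id))
}
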