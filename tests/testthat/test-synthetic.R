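# Synthetic generator: determinism, spectral contracts, composition rules,
# dataset writing.

test_that("shape field is deterministic, bounded, and low-frequency", {
  spec <- SyntheticClassSpec(0, blobRadius = 10, blobCenterJitter = 0)
  f1 <- renderShapeField(spec, 64, rngSeed = 7)
  f2 <- renderShapeField(spec, 64, rngSeed = 7)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  # essentially all spectral energy below 0.25 cycles/pixel
  expect_lt(spectralBandEnergy(f1, 0.25, 1, fraction = TRUE), 0.05)
})

test_that("centered blob is symmetric under 180-degree rotation", {
  spec <- SyntheticClassSpec(0, blobRadius = 16, blobRadiusSpread = 0,
                             blobCenterJitter = 0)
  f <- renderShapeField(spec, 64, rngSeed = 3)
  rot180 <- f[64:1, 64:1]
  expect_lt(max(abs(f - rot180)), 0.02)
})

test_that("larger blob radius yields strictly larger field energy", {
  small <- SyntheticClassSpec(0, blobRadius = 6, blobRadiusSpread = 0,
                              blobCenterJitter = 0)
  large <- SyntheticClassSpec(0, blobRadius = 12, blobRadiusSpread = 0,
                              blobCenterJitter = 0)
  eS <- sum(renderShapeField(small, 64, 5))
  eL <- sum(renderShapeField(large, 64, 5))
  expect_gt(eL, eS)
})

test_that("oversized blob raises an error naming the offending field", {
  spec <- SyntheticClassSpec(0, blobRadius = 30)
  expect_error(renderShapeField(spec, 64, 1), "blobRadius")
})

test_that("texture field peaks at the requested frequency bin", {
  spec <- SyntheticClassSpec(1, textureFreq = 0.25, textureOrientation = 30,
                             hfWeight = 1)
  f <- renderTextureField(spec, 64, rngSeed = 11)
  expect_lt(abs(mean(f)), 1e-10)
  p <- Mod(fft(f))^2
  rho <- df$fftFreqGrid(64)
  peak <- rho[which.max(p)]
  expect_lt(abs(peak * 64 - 0.25 * 64), 1 + 1e-9)   # within one bin of 16
})

test_that("frequencies beyond Nyquist are rejected", {
  expect_error(SyntheticClassSpec(0, textureFreq = 0.75), "Nyquist")
})

test_that("orientations 0 and 90 degrees give transposed fields", {
  s0 <- SyntheticClassSpec(0, textureFreq = 0.2, textureOrientation = 0)
  s90 <- SyntheticClassSpec(0, textureFreq = 0.2, textureOrientation = 90)
  f0 <- renderTextureField(s0, 64, rngSeed = 4)
  f90 <- renderTextureField(s90, 64, rngSeed = 4)
  expect_lt(max(abs(t(f0) - f90)), 1e-10)
})

test_that("composition follows image = clip(shape + w*texture + noise)", {
  # hfWeight 0, no noise: image equals the shape field exactly
  spec <- SyntheticClassSpec(2, hfWeight = 0, noiseSd = 0)
  s <- composeSample(spec, 64, rngSeed = 9)
  shape <- renderShapeField(spec, 64, df$hashSeeds(9, 1))
  expect_identical(s$image[, , 1], shape)
  expect_identical(s$image[, , 1], s$image[, , 3])
  expect_equal(s$classId, 2L)
  # pixels stay in range even with strong texture and noise
  noisy <- SyntheticClassSpec(3, hfWeight = 1, noiseSd = 0.3)
  s2 <- composeSample(noisy, 64, rngSeed = 10)
  expect_true(all(s2$image >= 0 & s2$image <= 1))
})

test_that("equal blobs with different textures share low-band energy only", {
  a <- SyntheticClassSpec(0, blobRadius = 9, blobEccentricity = 0.3,
                          textureFreq = 0.3, hfWeight = 1, noiseSd = 0)
  b <- SyntheticClassSpec(1, blobRadius = 9, blobEccentricity = 0.3,
                          textureFreq = 0.45, hfWeight = 1, noiseSd = 0)
  seeds <- 1:12
  lowA <- mean(sapply(seeds, function(s)
    spectralBandEnergy(composeSample(a, 64, s)$image[, , 1], 0, 0.1)))
  lowB <- mean(sapply(seeds, function(s)
    spectralBandEnergy(composeSample(b, 64, s)$image[, , 1], 0, 0.1)))
  expect_lt(abs(lowA - lowB) / lowA, 0.02)
  hiA <- mean(sapply(seeds, function(s)
    spectralBandEnergy(composeSample(a, 64, s)$image[, , 1], 0.25, 0.36)))
  hiB <- mean(sapply(seeds, function(s)
    spectralBandEnergy(composeSample(b, 64, s)$image[, , 1], 0.25, 0.36)))
  expect_gt(hiA, 3 * hiB)   # the 0.3 c/p grating lives in this band
})

test_that("dataset generation writes counted, byte-identical, order-independent files", {
  specs <- defaultClassSpecs("mixed")
  d1 <- file.path(tempdir(), "synth1")
  d2 <- file.path(tempdir(), "synth2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(specs, nPerClass = 3, size = 64, masterSeed = 99, outDir = d1)
  expect_equal(nrow(m1@samples), 12)
  expect_equal(unname(table(m1@samples$class_id)), rep(3L, 4), ignore_attr = TRUE)
  # regeneration with shuffled spec order: same bytes per file
  m2 <- generateDataset(rev(specs), nPerClass = 3, size = 64, masterSeed = 99, outDir = d2)
  for (p in m1@samples$path) {
    expect_identical(readBin(file.path(d1, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
  }
  # manifest round trip into a tensor
  td <- loadSyntheticDataset(m1)
  expect_equal(dim(td$x), c(12, 3, 64, 64))
  expect_equal(sort(unique(td$y)), 0:3)
})

test_that("in-memory tensors match the on-disk dataset up to 8-bit quantisation", {
  specs <- defaultClassSpecs("shape")[1:2]
  d <- file.path(tempdir(), "synth3")
  unlink(d, recursive = TRUE)
  m <- generateDataset(specs, nPerClass = 2, size = 64, masterSeed = 5, outDir = d)
  mem <- synthesizeTensors(specs, nPerClass = 2, size = 64, masterSeed = 5)
  disk <- loadSyntheticDataset(m)
  expect_equal(disk$y, mem$y)
  expect_lt(max(abs(disk$x - mem$x)), 1 / 255)
})

test_that("frequency disentanglement: class signal sits in the stated band", {
  # shape-only data: between-class divergence above 0.25 c/p is noise-level
  nPer <- 25
  highE <- function(specs) sapply(seq_along(specs), function(i)
    sapply(seq_len(nPer), function(j)
      spectralBandEnergy(composeSample(specs[[i]], 64,
                                       df$hashSeeds(17, i, j))$image[, , 1],
                         0.25, 0.71)))
  lowE <- function(specs) sapply(seq_along(specs), function(i)
    sapply(seq_len(nPer), function(j)
      spectralBandEnergy(composeSample(specs[[i]], 64,
                                       df$hashSeeds(17, i, j))$image[, , 1],
                         0, 0.1)))
  permP <- function(e) {
    # permutation test on the between-class F statistic
    y <- rep(seq_len(ncol(e)), each = nrow(e))
    v <- as.numeric(e)
    fstat <- function(lab) {
      mu <- tapply(v, lab, mean)
      sum(tabulate(lab) * (mu - mean(v))^2)
    }
    obs <- fstat(y)
    set.seed(1)
    null <- replicate(200, fstat(sample(y)))
    mean(null >= obs)
  }
  shapeSpecs <- defaultClassSpecs("shape", noiseSd = 0.05)
  pHighShape <- permP(highE(shapeSpecs))
  expect_gt(pHighShape, 0.05)    # indistinguishable from noise
  pLowShape <- permP(lowE(shapeSpecs))
  expect_lt(pLowShape, 0.01)     # the shape signal is low-frequency
  # texture-only data with identical blobs: high band significant
  texSpecs <- defaultClassSpecs("texture", noiseSd = 0.05)
  pHighTex <- permP(highE(texSpecs))
  expect_lt(pHighTex, 0.01)
})
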