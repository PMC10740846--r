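# Residual backbones: identity behaviour, stride contracts, the multi-scale
# bottleneck's degeneracy to a plain bottleneck, output shapes, checkpoints.

test_that("zero-weight residual block with identity shortcut is the identity", {
  blk <- residualBlock(4, 4)
  zeroAllParams(blk)
  x <- abs(randomImageTensor(1, 4, 8, 8, seed = 21))  # positive: post-ReLU safe
  y <- df$moduleForward(blk, x)
  expect_equal(y, x)
})

test_that("stride-2 blocks halve the spatial dimensions", {
  blk <- residualBlock(4, 8, stride = 2)
  x <- randomImageTensor(1, 4, 8, 8, seed = 22)
  expect_equal(dim(df$moduleForward(blk, x)), c(1, 8, 4, 4))
  r2 <- res2Block(4, 4, stride = 2, scale = 4)
  expect_equal(dim(df$moduleForward(r2, x)), c(1, 16, 4, 4))
})

test_that("incompatible shapes without a projection raise a shape error", {
  body <- df$nnSeq(df$nnConv(4L, 8L, 3))
  blk <- df$nnResidual(body, shortcut = NULL)
  expect_error(df$moduleForward(blk, randomImageTensor(1, 4, 8, 8)),
               "incompatible")
})

test_that("residual block output equals brute-force composition of its convs", {
  # batch norm set to pass-through (gamma 1, beta 0, unit running stats) in
  # inference mode, so the block is conv -> relu -> conv plus the shortcut
  blk <- residualBlock(4, 4)
  x <- randomImageTensor(1, 4, 8, 8, seed = 23)
  convs <- Filter(function(m) m$type == "conv",
                  df$collectParamModules(blk))
  sc <- 1 / sqrt(1 + 1e-5)   # inference rescale by running var + eps
  h <- bruteForceConv(x, convs[[1]]$w, convs[[1]]$b) * sc
  h <- h * (h > 0)
  h <- bruteForceConv(h, convs[[2]]$w, convs[[2]]$b) * sc
  want <- (h + x) * ((h + x) > 0)
  got <- df$moduleForward(blk, x, training = FALSE)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("scale-1 multi-scale bottleneck equals a standard bottleneck", {
  set.seed(24)
  r2 <- res2Block(8, 4, scale = 1)
  # independently assembled standard bottleneck from engine primitives:
  # conv1x1 -> bn -> relu -> conv3x3 -> bn -> relu -> conv1x1 -> bn,
  # projection shortcut, relu after the addition
  body <- df$nnSeq(df$nnConv(8L, 4L, 1, pad = 0), df$nnBatchNorm(4L), df$nnReLU(),
                   df$nnConv(4L, 4L, 3), df$nnBatchNorm(4L), df$nnReLU(),
                   df$nnConv(4L, 16L, 1, pad = 0), df$nnBatchNorm(16L))
  short <- df$nnSeq(df$nnConv(8L, 16L, 1, pad = 0), df$nnBatchNorm(16L))
  bot <- df$nnResidual(body, short)
  # copy the multi-scale block's weights into the hand-assembled bottleneck
  body$layers[[1]]$w <- r2$conv1$w;  body$layers[[1]]$b <- r2$conv1$b
  body$layers[[4]]$w <- r2$convs[[1]]$w; body$layers[[4]]$b <- r2$convs[[1]]$b
  body$layers[[7]]$w <- r2$conv3$w;  body$layers[[7]]$b <- r2$conv3$b
  short$layers[[1]]$w <- r2$shortcut$layers[[1]]$w
  short$layers[[1]]$b <- r2$shortcut$layers[[1]]$b
  x <- randomImageTensor(2, 8, 6, 6, seed = 25)
  expect_lt(max(abs(df$moduleForward(r2, x) - df$moduleForward(bot, x))), 1e-5)
})

test_that("zero-weight multi-scale bottleneck with identity shortcut is identity", {
  r2 <- res2Block(16, 4, scale = 4)   # out = 4 * 4 = 16 = in, no projection
  expect_null(r2$shortcut)
  zeroAllParams(r2)
  x <- abs(randomImageTensor(1, 16, 6, 6, seed = 26))
  expect_equal(df$moduleForward(r2, x), x)
})

test_that("hierarchical groups chain receptive fields (3 convs span 7x7)", {
  r2 <- res2Block(16, 16, scale = 4)
  # remove batch norm scaling effects: set all bn to identity and biases 0
  for (m in df$collectParamModules(r2))
    if (m$type == "bn") { m$runMean <- m$runMean * 0; m$runVar <- m$runVar * 0 + 1 }
  x <- array(0, c(1, 16, 15, 15))
  x[1, , 8, 8] <- 1   # impulse at the centre
  y <- df$moduleForward(r2, x)
  resp <- apply(abs(y), c(3, 4), sum)
  on <- which(resp > 1e-8, arr.ind = TRUE)
  span <- c(diff(range(on[, 1])), diff(range(on[, 2]))) + 1
  # deepest group chains three 3x3 convolutions -> 7x7 footprint
  expect_true(all(span == 7))
})

test_that("backbones meet their output-shape contracts", {
  set.seed(27)
  tiny <- buildBackbone(BackboneConfig("resnet", "tiny"))
  expect_equal(dim(forwardPass(tiny, array(0, c(3, 64, 64)))), c(32, 4, 4))
  expect_equal(dim(forwardPass(tiny, array(0, c(3, 256, 256)))), c(32, 16, 16))
  r18 <- buildBackbone(BackboneConfig("resnet", "18"))
  expect_equal(dim(forwardPass(r18, array(0, c(3, 256, 256)))), c(512, 8, 8))
  expect_error(buildBackbone(BackboneConfig("resnet", "34")), "depth")
})

test_that("res2net-50 maps 3x256x256 to 2048x8x8", {
  set.seed(28)
  r50 <- buildBackbone(BackboneConfig("res2net", "50", res2Scale = 4))
  expect_equal(dim(forwardPass(r50, array(0, c(3, 256, 256)))), c(2048, 8, 8))
})

test_that("checkpoints round-trip and fail loudly on mismatch", {
  set.seed(29)
  bb <- buildBackbone(BackboneConfig("resnet", "tiny"))
  x <- randomImageTensor(1, 3, 64, 64, seed = 30)
  y0 <- df$moduleForward(bb, x)
  ck <- tempfile(fileext = ".rds")
  saveModelWeights(bb, ck)
  # perturb, reload, verify restoration
  for (m in df$collectParamModules(bb))
    for (p in m$params) m[[p]] <- m[[p]] + 0.5
  loadExternalWeights(bb, ck)
  expect_equal(df$moduleForward(bb, x), y0)
  # saved tensors are byte-equivalent after a save/load/save cycle
  ck2 <- tempfile(fileext = ".rds")
  saveModelWeights(bb, ck2)
  expect_identical(readRDS(ck), readRDS(ck2))
  # missing file and truncated checkpoint
  expect_error(loadExternalWeights(bb, tempfile()), "not found")
  tr <- readRDS(ck)
  bad <- tr[-1]
  ck3 <- tempfile(fileext = ".rds")
  saveRDS(bad, ck3)
  expect_error(loadExternalWeights(bb, ck3), names(tr)[1], fixed = TRUE)
  # shape mismatch names the offending tensor
  tr2 <- tr
  tr2[[2]] <- array(0, c(2, 2))
  saveRDS(tr2, ck3)
  expect_error(loadExternalWeights(bb, ck3), "shape")
  # a randomly initialised extractor runs without any checkpoint
  fresh <- buildBackbone(BackboneConfig("resnet", "tiny"))
  expect_silent(df$moduleForward(fresh, x))
})
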