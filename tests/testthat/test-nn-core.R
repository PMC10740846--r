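# Engine primitives: convolution against a brute-force oracle, analytic
# gradients against central differences, pooling, pixel shuffle, bilinear
# upsampling.

test_that("convolution matches the brute-force sliding-window oracle", {
  set.seed(11)
  x <- randomImageTensor(2, 3, 9, 9)
  w <- array(rnorm(4 * 3 * 3 * 3), c(4, 3, 3, 3))
  b <- rnorm(4)
  for (d in c(1L, 3L, 5L)) {
    got <- df$cpp_conv2d_fwd(x, w, b, 1L, d, d)$y
    want <- bruteForceConv(x, w, b, 1, d, d)
    expect_lt(max(abs(got - want)), 1e-6)
  }
  gotS <- df$cpp_conv2d_fwd(x, w, b, 2L, 1L, 1L)$y
  expect_lt(max(abs(gotS - bruteForceConv(x, w, b, 2, 1, 1))), 1e-6)
  expect_equal(dim(gotS), c(2, 4, 5, 5))
})

test_that("convolution backward matches numeric gradients (with and without cache)", {
  set.seed(12)
  x <- randomImageTensor(2, 2, 6, 6)
  w <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  b <- rnorm(3)
  fwd <- df$cpp_conv2d_fwd(x, w, b, 1L, 1L, 1L, TRUE)
  g <- array(rnorm(length(fwd$y)), dim(fwd$y))
  bw <- df$cpp_conv2d_bwd(x, w, g, 1L, 1L, 1L)
  bwC <- df$cpp_conv2d_bwd(x, w, g, 1L, 1L, 1L, fwd$xcol)
  expect_identical(bw, bwC)
  nx <- numericGradient(function(z) sum(df$cpp_conv2d_fwd(z, w, b, 1L, 1L, 1L)$y * g), x)
  nw <- numericGradient(function(z) sum(df$cpp_conv2d_fwd(x, z, b, 1L, 1L, 1L)$y * g), w)
  expect_lt(max(abs(nx - bw$dx[seq_along(nx)])), 1e-6)
  expect_lt(max(abs(nw - bw$dw[seq_along(nw)])), 1e-6)
})

test_that("composite blocks backpropagate exact gradients", {
  set.seed(13)
  x <- randomImageTensor(2, 4, 8, 8)
  for (maker in list(function() msdcResidualBlock(4),
                     function() attentionBlock(4),
                     function() residualBlock(4, 4),
                     function() res2Block(4, 8, scale = 4))) {
    m <- maker()
    y <- df$moduleForward(m, x, training = TRUE)
    g <- array(rnorm(length(y)), dim(y))
    df$zeroGrads(df$collectParamModules(m))
    dx <- df$moduleBackward(m, g)
    # batch-norm layers make the forward depend on batch statistics, so the
    # numeric probe also runs in training mode
    nf <- function(z) sum(df$moduleForward(m, z, training = TRUE) * g)
    nx <- numericGradient(nf, x)
    expect_lt(max(abs(nx - dx[seq_along(nx)])), 1e-5)
  }
})

test_that("average and max pooling behave and differentiate correctly", {
  set.seed(14)
  x <- randomImageTensor(2, 3, 8, 8)
  y <- df$cpp_avgpool_fwd(x, 4L)
  expect_equal(dim(y), c(2, 3, 2, 2))
  expect_equal(y[1, 1, 1, 1], mean(x[1, 1, 1:4, 1:4]))
  dy <- array(rnorm(length(y)), dim(y))
  dx <- df$cpp_avgpool_bwd(dy, 4L)
  nx <- numericGradient(function(z) sum(df$cpp_avgpool_fwd(z, 4L) * dy), x)
  expect_lt(max(abs(nx - dx[seq_along(nx)])), 1e-7)

  mp <- df$cpp_maxpool_fwd(x, 3L, 2L, 1L)
  expect_equal(dim(mp$y), c(2, 3, 4, 4))
  dxm <- df$cpp_maxpool_bwd(array(1, dim(mp$y)), mp$argmax, dim(x))
  expect_equal(sum(dxm), prod(dim(mp$y)))
})

test_that("pixel shuffle is a value-preserving permutation with exact inverse", {
  set.seed(15)
  x <- array(rnorm(4 * 2 * 2), c(4, 2, 2))
  y <- subpixelUpsample(x, 2)
  expect_equal(dim(y), c(1, 4, 4))
  expect_equal(sort(as.numeric(y)), sort(as.numeric(x)))
  expect_identical(spaceToChannel(y, 2), x)
  expect_identical(subpixelUpsample(x, 1), x)
  expect_error(subpixelUpsample(array(0, c(3, 2, 2)), 2), "divisible")
  # known layout: channel c*r^2 + i*r + j lands at (h*r+i, w*r+j)
  z <- array(0, c(4, 1, 1)); z[2, 1, 1] <- 1   # c=0, i=0, j=1
  u <- subpixelUpsample(z, 2)                  # -> 1 x 2 x 2 map, position (1, 2)
  expect_equal(u[1, 1, 2], 1)
  expect_equal(sum(u), 1)
})

test_that("bilinear upsampling is exact on constants and differentiates", {
  up <- df$nnBilinearUp(8L, 8L)
  x <- array(0.7, c(1, 2, 4, 4))
  y <- df$moduleForward(up, x)
  expect_equal(dim(y), c(1, 2, 8, 8))
  expect_lt(max(abs(y - 0.7)), 1e-12)
  set.seed(16)
  x <- randomImageTensor(1, 2, 4, 4)
  y <- df$moduleForward(up, x)
  g <- array(rnorm(length(y)), dim(y))
  dx <- df$moduleBackward(up, g)
  nx <- numericGradient(function(z) sum(df$moduleForward(up, z) * g), x)
  expect_lt(max(abs(nx - dx[seq_along(nx)])), 1e-7)
})

test_that("training a linearly separable problem reaches perfect accuracy", {
  set.seed(17)
  n <- 40
  x <- rbind(matrix(rnorm(n * 4, mean = 1.5), n, 4),
             matrix(rnorm(n * 4, mean = -1.5), n, 4))
  y <- rep(c(0L, 1L), each = n)
  head <- fusionHead(4, 2, dropout = 0)
  curves <- trainNetwork(head, x, y,
                         config = TrainConfig(batchSize = 8, epochs = 20,
                                              lr = 5e-3, dropout = 0,
                                              seed = 1, logEvery = 5,
                                              imageSize = 4))
  expect_equal(tail(curves$trainAcc, 1), 1.0)
})
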