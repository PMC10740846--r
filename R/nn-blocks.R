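# Composite modules: residual blocks, the multi-scale (Res2-style) bottleneck,
# channel/pixel attention, the multi-stream dilated-convolution block and the
# multi-scale enhancing block.  Each has a hand-derived backward pass.

nnSigmoid <- function() newModule("sigmoid")

# per-sample-per-channel broadcast of an (N, C) matrix over (N, C, H, W);
# relies on (n, c) being the fastest-varying dims of the NCHW layout
bcSampleChannel <- function(g, d) array(as.numeric(g), dim = d)

# ---- residual blocks --------------------------------------------------------

nnResidual <- function(body, shortcut = NULL, postRelu = TRUE)
  newModule("residual", body = body, shortcut = shortcut, postRelu = postRelu)

forwardResidual <- function(m, x, training) {
  s <- if (is.null(m$shortcut)) x else moduleForward(m$shortcut, x, training)
  h <- moduleForward(m$body, x, training)
  if (!identical(dim(h), dim(s)))
    stop("residual block: transform output [", paste(dim(h), collapse = "x"),
         "] and shortcut [", paste(dim(s), collapse = "x"),
         "] are incompatible and no projection is configured")
  y <- h + s
  if (m$postRelu) { m$cacheMask <- (y > 0); y <- y * m$cacheMask }
  y
}

backwardResidual <- function(m, dy) {
  if (m$postRelu) dy <- dy * m$cacheMask
  dxb <- moduleBackward(m$body, dy)
  dxs <- if (is.null(m$shortcut)) dy else moduleBackward(m$shortcut, dy)
  dxb + dxs
}

makeBasicBlock <- function(inC, outC, stride = 1L) {
  body <- nnSeq(nnConv(inC, outC, 3, stride = stride), nnBatchNorm(outC),
                nnReLU(), nnConv(outC, outC, 3), nnBatchNorm(outC))
  shortcut <- if (stride != 1L || inC != outC)
    nnSeq(nnConv(inC, outC, 1, stride = stride, pad = 0), nnBatchNorm(outC))
  nnResidual(body, shortcut)
}

# ---- multi-scale (Res2-style) bottleneck ------------------------------------

nnRes2Block <- function(inC, planes, stride = 1L, scale = 1L, expansion = 4L) {
  if (planes %% scale != 0L)
    stop("res2 block: inner width ", planes, " is not divisible by scale ", scale)
  outC <- planes * expansion
  gw <- planes %/% scale
  nConv <- if (scale == 1L) 1L else scale - 1L
  convs <- lapply(seq_len(nConv), function(i) nnConv(gw, gw, 3, stride = stride))
  bns <- lapply(seq_len(nConv), function(i) nnBatchNorm(gw))
  shortcut <- if (stride != 1L || inC != outC)
    nnSeq(nnConv(inC, outC, 1, stride = stride, pad = 0), nnBatchNorm(outC))
  newModule("res2",
            conv1 = nnConv(inC, planes, 1, pad = 0), bn1 = nnBatchNorm(planes),
            convs = convs, bns = bns,
            conv3 = nnConv(planes, outC, 1, pad = 0), bn3 = nnBatchNorm(outC),
            shortcut = shortcut, poolG1 = nnAvgPool(max(stride, 1L)),
            scale = as.integer(scale), stride = as.integer(stride),
            groupWidth = as.integer(gw), outChannels = as.integer(outC))
}

forwardRes2 <- function(m, x, training) {
  s <- m$scale
  h <- moduleForward(m$conv1, x, training)
  h <- moduleForward(m$bn1, h, training)
  m$mask1 <- (h > 0); h <- h * m$mask1
  gw <- m$groupWidth
  masks <- vector("list", s)
  if (s == 1L) {
    y1 <- moduleForward(m$bns[[1]], moduleForward(m$convs[[1]], h, training), training)
    masks[[1]] <- (y1 > 0)
    z <- y1 * masks[[1]]
  } else {
    ys <- vector("list", s)
    for (i in seq_len(s)) {
      xi <- h[, (i - 1L) * gw + seq_len(gw), , , drop = FALSE]
      if (i == 1L) {
        ys[[i]] <- if (m$stride == 1L) xi else moduleForward(m$poolG1, xi, training)
      } else {
        inp <- if (i >= 3L && m$stride == 1L) xi + ys[[i - 1L]] else xi
        yi <- moduleForward(m$bns[[i - 1L]],
                            moduleForward(m$convs[[i - 1L]], inp, training), training)
        masks[[i]] <- (yi > 0)
        ys[[i]] <- yi * masks[[i]]
      }
    }
    z <- ys[[1]]
    for (i in 2:s) z <- catChannels(z, ys[[i]])
  }
  m$groupMasks <- masks
  o <- moduleForward(m$bn3, moduleForward(m$conv3, z, training), training)
  sc <- if (is.null(m$shortcut)) x else moduleForward(m$shortcut, x, training)
  y <- o + sc
  m$maskPost <- (y > 0)
  y * m$maskPost
}

backwardRes2 <- function(m, dy) {
  s <- m$scale
  gw <- m$groupWidth
  dy <- dy * m$maskPost
  dsc <- if (is.null(m$shortcut)) dy else moduleBackward(m$shortcut, dy)
  dz <- moduleBackward(m$conv3, moduleBackward(m$bn3, dy))
  if (s == 1L) {
    d1 <- dz * m$groupMasks[[1]]
    dh <- moduleBackward(m$convs[[1]], moduleBackward(m$bns[[1]], d1))
  } else {
    dys <- lapply(seq_len(s), function(i)
      dz[, (i - 1L) * gw + seq_len(gw), , , drop = FALSE])
    dxs <- vector("list", s)
    for (i in s:2) {
      di <- dys[[i]] * m$groupMasks[[i]]
      dinp <- moduleBackward(m$convs[[i - 1L]], moduleBackward(m$bns[[i - 1L]], di))
      dxs[[i]] <- dinp
      if (i >= 3L && m$stride == 1L) dys[[i - 1L]] <- dys[[i - 1L]] + dinp
    }
    dxs[[1]] <- if (m$stride == 1L) dys[[1]] else moduleBackward(m$poolG1, dys[[1]])
    dh <- dxs[[1]]
    for (i in 2:s) dh <- catChannels(dh, dxs[[i]])
  }
  dh <- dh * m$mask1
  dx <- moduleBackward(m$conv1, moduleBackward(m$bn1, dh))
  dx + dsc
}

# ---- channel / pixel attention ---------------------------------------------

nnChannelAttention <- function(C, reduction = 4L) {
  mid <- max(2L, C %/% reduction)
  newModule("ca", fc1 = nnLinear(C, mid), fc2 = nnLinear(mid, C))
}

forwardCA <- function(m, x, training) {
  d <- dim(x)
  m$cacheX <- x
  p <- matrix(rowMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[1], d[2])
  h <- moduleForward(m$fc1, p, training)
  m$maskH <- (h > 0)
  z <- moduleForward(m$fc2, h * m$maskH, training)
  g <- 1 / (1 + exp(-z))
  m$cacheG <- g
  x * bcSampleChannel(g, d)
}

backwardCA <- function(m, dy) {
  d <- dim(dy)
  x <- m$cacheX
  g <- m$cacheG
  dg <- matrix(rowSums(matrix(dy * x, d[1] * d[2], d[3] * d[4])), d[1], d[2])
  dz <- dg * g * (1 - g)
  dh <- moduleBackward(m$fc2, dz) * m$maskH
  dp <- moduleBackward(m$fc1, dh)
  dy * bcSampleChannel(g, d) + bcSampleChannel(dp / (d[3] * d[4]), d)
}

nnPixelAttention <- function(C, reduction = 4L) {
  mid <- max(2L, C %/% reduction)
  newModule("pa", conv1 = nnConv(C, mid, 1, pad = 0), conv2 = nnConv(mid, 1, 1, pad = 0))
}

expandGate <- function(g, d) {
  # g: (N, 1, H, W) -> (N, C, H, W)
  g3 <- array(g, dim = c(d[1], d[3], d[4]))
  aperm(array(g3, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

sumChannelsKeep <- function(x) {
  d <- dim(x)
  arr <- aperm(x, c(2, 1, 3, 4))
  s <- colSums(matrix(arr, d[2], d[1] * d[3] * d[4]))
  array(s, dim = c(d[1], 1L, d[3], d[4]))
}

forwardPA <- function(m, x, training) {
  d <- dim(x)
  m$cacheX <- x
  a <- moduleForward(m$conv1, x, training)
  m$maskA <- (a > 0)
  z <- moduleForward(m$conv2, a * m$maskA, training)
  g <- 1 / (1 + exp(-z))
  m$cacheG <- g
  x * expandGate(g, d)
}

backwardPA <- function(m, dy) {
  d <- dim(dy)
  x <- m$cacheX
  g <- m$cacheG
  dgate <- sumChannelsKeep(dy * x)
  dz <- dgate * g * (1 - g)
  da <- moduleBackward(m$conv2, dz) * m$maskA
  dx2 <- moduleBackward(m$conv1, da)
  dy * expandGate(g, d) + dx2
}

# ---- feature-attention block (local residual around conv + CA + PA) ---------

nnAttentionBlock <- function(C) {
  newModule("attnblock", c1 = nnConv(C, C, 3), c2 = nnConv(C, C, 3),
            ca = nnChannelAttention(C), pa = nnPixelAttention(C))
}

forwardAttnBlock <- function(m, x, training) {
  t1 <- moduleForward(m$c1, x, training)
  m$maskT <- (t1 > 0)
  t2 <- moduleForward(m$c2, t1 * m$maskT, training)
  u <- moduleForward(m$ca, t2, training)
  v <- moduleForward(m$pa, u, training)
  x + v
}

backwardAttnBlock <- function(m, dy) {
  du <- moduleBackward(m$pa, dy)
  dt2 <- moduleBackward(m$ca, du)
  dt1 <- moduleBackward(m$c2, dt2) * m$maskT
  dx2 <- moduleBackward(m$c1, dt1)
  dy + dx2
}

# ---- multi-stream dilated convolution ---------------------------------------

nnMSDC <- function(C, dilations = c(1L, 3L, 5L)) {
  if (!identical(as.integer(dilations), c(1L, 3L, 5L)))
    stop("the multi-stream block uses dilation rates 1, 3, 5 exactly")
  newModule("msdc",
            d1 = nnConv(C, C, 3, dilation = 1L),
            d3 = nnConv(C, C, 3, dilation = 3L),
            d5 = nnConv(C, C, 3, dilation = 5L),
            f13 = nnConv(2L * C, C, 1, pad = 0),
            f35 = nnConv(2L * C, C, 1, pad = 0),
            # zero-initialised fusion: the residual block starts as the
            # identity, which stabilises training of the normalisation-free
            # low-frequency branch
            fout = nnConv(2L * C, C, 1, pad = 0, zeroInit = TRUE),
            channels = as.integer(C))
}

forwardMSDC <- function(m, x, training) {
  if (dim(x)[2] != m$channels)
    stop("multi-stream block expects ", m$channels, " channels, got ", dim(x)[2])
  D1 <- moduleForward(m$d1, x, training)
  D3 <- moduleForward(m$d3, x, training)   # computed once, shared by both pairs
  D5 <- moduleForward(m$d5, x, training)
  a <- moduleForward(m$f13, catChannels(D1, D3), training)
  m$mask13 <- (a > 0)
  b <- moduleForward(m$f35, catChannels(D3, D5), training)
  m$mask35 <- (b > 0)
  moduleForward(m$fout, catChannels(a * m$mask13, b * m$mask35), training)
}

backwardMSDC <- function(m, dy) {
  C <- m$channels
  dcat <- moduleBackward(m$fout, dy)
  da <- dcat[, seq_len(C), , , drop = FALSE] * m$mask13
  db <- dcat[, C + seq_len(C), , , drop = FALSE] * m$mask35
  d13 <- moduleBackward(m$f13, da)
  d35 <- moduleBackward(m$f35, db)
  dD1 <- d13[, seq_len(C), , , drop = FALSE]
  dD3 <- d13[, C + seq_len(C), , , drop = FALSE] + d35[, seq_len(C), , , drop = FALSE]
  dD5 <- d35[, C + seq_len(C), , , drop = FALSE]
  moduleBackward(m$d1, dD1) + moduleBackward(m$d3, dD3) + moduleBackward(m$d5, dD5)
}

nnMSDCRB <- function(C, dilations = c(1L, 3L, 5L))
  newModule("msdcrb", body = nnMSDC(C, dilations))

# ---- multi-scale enhancing block --------------------------------------------

nnEnhancingBlock <- function(C, poolSizes = c(4L, 8L, 16L, 32L)) {
  redC <- max(1L, C %/% 4L)
  newModule("enhancing",
            c1 = nnConv(C, C, 3), c2 = nnConv(C, C, 3),
            pools = lapply(poolSizes, nnAvgPool),
            reducers = lapply(poolSizes, function(k) nnConv(C, redC, 1, pad = 0)),
            ups = lapply(poolSizes, function(k) nnBilinearUp(1L, 1L)),
            fuse = nnConv(C + length(poolSizes) * redC, C, 3),
            poolSizes = as.integer(poolSizes), redC = redC,
            channels = as.integer(C))
}

forwardEnhancing <- function(m, x, training) {
  d <- dim(x)
  H <- d[3]; W <- d[4]
  if (H < max(m$poolSizes) || W < max(m$poolSizes))
    stop("enhancing block: spatial size ", H, "x", W,
         " is smaller than the largest pooling kernel (", max(m$poolSizes), ")")
  z <- moduleForward(m$c2, moduleForward(m$c1, x, training), training)
  parts <- z
  for (i in seq_along(m$pools)) {
    p <- moduleForward(m$pools[[i]], z, training)
    r <- moduleForward(m$reducers[[i]], p, training)
    m$ups[[i]]$targetH <- H
    m$ups[[i]]$targetW <- W
    u <- moduleForward(m$ups[[i]], r, training)
    parts <- catChannels(parts, u)
  }
  moduleForward(m$fuse, parts, training)
}

backwardEnhancing <- function(m, dy) {
  C <- m$channels
  redC <- m$redC
  dparts <- moduleBackward(m$fuse, dy)
  dz <- dparts[, seq_len(C), , , drop = FALSE]
  for (i in seq_along(m$pools)) {
    du <- dparts[, C + (i - 1L) * redC + seq_len(redC), , , drop = FALSE]
    dr <- moduleBackward(m$ups[[i]], du)
    dp <- moduleBackward(m$reducers[[i]], dr)
    dz <- dz + moduleBackward(m$pools[[i]], dp)
  }
  moduleBackward(m$c1, moduleBackward(m$c2, dz))
}
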