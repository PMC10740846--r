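# Compact CNN engine: layers are mutable environments holding parameters,
# gradients and the forward cache needed by the analytic backward pass.
# Tensors are plain R arrays with dim = c(N, C, H, W).

newModule <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  if (is.null(e$params)) e$params <- character(0)
  e$grad <- list()
  class(e) <- c(paste0("df_", type), "dfModule")
  e
}

#' @export
print.dfModule <- function(x, ...) {
  np <- sum(vapply(collectParamModules(x), function(m) {
    sum(vapply(m$params, function(p) length(m[[p]]), numeric(1)))
  }, numeric(1)))
  cat(sprintf("<dfModule: %s, %s parameters>\n", x$type, format(np, big.mark = ",")))
  invisible(x)
}

heInitConv <- function(co, ci, k) {
  array(stats::rnorm(co * ci * k * k, 0, sqrt(2 / (ci * k * k))), dim = c(co, ci, k, k))
}

# ---- layer constructors -----------------------------------------------------

nnConv <- function(inC, outC, k = 3L, stride = 1L, pad = NULL, dilation = 1L,
                   zeroInit = FALSE) {
  if (is.null(pad)) pad <- (k %/% 2L) * dilation
  w <- if (zeroInit) array(0, c(outC, inC, k, k)) else heInitConv(outC, inC, k)
  newModule("conv", w = w, b = numeric(outC),
            stride = as.integer(stride), pad = as.integer(pad),
            dilation = as.integer(dilation), params = c("w", "b"))
}

nnBatchNorm <- function(C, momentum = 0.1, eps = 1e-5) {
  newModule("bn", gamma = rep(1, C), beta = numeric(C),
            runMean = numeric(C), runVar = rep(1, C),
            momentum = momentum, eps = eps, params = c("gamma", "beta"))
}

nnReLU <- function() newModule("relu")
nnAvgPool <- function(k) newModule("avgpool", k = as.integer(k))
nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L)
  newModule("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
nnGlobalAvgPool <- function() newModule("gap")
nnFlatten <- function() newModule("flatten")
nnDropout <- function(p) newModule("dropout", p = p)

nnLinear <- function(inF, outF, zeroInit = FALSE) {
  w <- if (zeroInit) matrix(0, outF, inF) else
    matrix(stats::rnorm(outF * inF, 0, sqrt(2 / inF)), outF, inF)
  newModule("linear", w = w, b = numeric(outF), params = c("w", "b"))
}

nnSeq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !inherits(layers[[1]], "dfModule"))
    layers <- layers[[1]]
  newModule("seq", layers = layers)
}

nnPixelShuffle <- function(r) newModule("pixelshuffle", r = as.integer(r))

# Bilinear upsampling to a fixed target size (differentiable; separable
# interpolation expressed as  Y = A X B').
nnBilinearUp <- function(targetH, targetW) {
  newModule("bilinearup", targetH = as.integer(targetH),
            targetW = as.integer(targetW))
}

# ---- broadcasting helpers ---------------------------------------------------

# expand a per-channel vector to an (N, C, H, W) array
bcChannel <- function(v, d) {
  aperm(array(v, dim = c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
}

# per-channel sums of an (N, C, H, W) array -> length C
channelSum <- function(x) {
  d <- dim(x)
  colSums(matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2]))
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[3] == db[3], da[4] == db[4])
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- a
  out[, da[2] + seq_len(db[2]), , ] <- b
  out
}

bilinearMatrix <- function(outN, inN) {
  A <- matrix(0, outN, inN)
  if (inN == 1L) { A[, 1] <- 1; return(A) }
  for (o in seq_len(outN)) {
    src <- (o - 0.5) * inN / outN - 0.5   # 0-based source coordinate
    i0 <- floor(src)
    frac <- src - i0
    lo <- min(max(i0, 0), inN - 1)
    hi <- min(max(i0 + 1, 0), inN - 1)
    A[o, lo + 1] <- A[o, lo + 1] + (1 - frac)
    A[o, hi + 1] <- A[o, hi + 1] + frac
  }
  A
}

pixelShuffleForward <- function(x, r) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (C %% (r * r) != 0L)
    stop("subpixel upsample: ", C, " channels not divisible by r^2 = ", r * r)
  if (r == 1L) return(x)
  Co <- C %/% (r * r)
  # channel index c_in = c_out*r^2 + i*r + j maps to output (h*r+i, w*r+j)
  dim(x) <- c(N, r, r, Co, H, W)          # (N, j, i, c, H, W)
  y <- aperm(x, c(1, 4, 3, 5, 2, 6))      # (N, c, i, H, j, W)
  dim(y) <- c(N, Co, r * H, r * W)
  y
}

pixelShuffleBackward <- function(dy, r) {
  if (r == 1L) return(dy)
  d <- dim(dy)
  N <- d[1]; Co <- d[2]; Ho <- d[3]; Wo <- d[4]
  H <- Ho %/% r; W <- Wo %/% r
  dim(dy) <- c(N, Co, r, H, r, W)         # (N, c, i, H, j, W)
  dx <- aperm(dy, c(1, 5, 3, 2, 4, 6))    # (N, j, i, c, H, W)
  dim(dx) <- c(N, Co * r * r, H, W)
  dx
}

# ---- forward ----------------------------------------------------------------

moduleForward <- function(m, x, training = FALSE) {
  switch(m$type,
    conv = {
      m$cacheX <- x
      r <- cpp_conv2d_fwd(x, m$w, m$b, m$stride, m$pad, m$dilation,
                          keepCols = training)
      m$cacheCols <- r$xcol
      r$y
    },
    bn = {
      d <- dim(x)
      if (training) {
        xm <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2])
        mu <- colMeans(xm)
        va <- colMeans(xm^2) - mu^2
        m$runMean <- (1 - m$momentum) * m$runMean + m$momentum * mu
        m$runVar <- (1 - m$momentum) * m$runVar + m$momentum * va
      } else {
        mu <- m$runMean; va <- m$runVar
      }
      ivar <- 1 / sqrt(va + m$eps)
      xhat <- (x - bcChannel(mu, d)) * bcChannel(ivar, d)
      if (training) { m$cacheXhat <- xhat; m$cacheIvar <- ivar }
      xhat * bcChannel(m$gamma, d) + bcChannel(m$beta, d)
    },
    relu = { y <- x * (x > 0); m$cacheMask <- (x > 0); y },
    sigmoid = { y <- 1 / (1 + exp(-x)); m$cacheY <- y; y },
    avgpool = { m$inDim <- dim(x); cpp_avgpool_fwd(x, m$k) },
    maxpool = {
      m$inDim <- dim(x)
      r <- cpp_maxpool_fwd(x, m$k, m$stride, m$pad)
      m$cacheArg <- r$argmax
      r$y
    },
    gap = {
      d <- dim(x); m$inDim <- d
      y <- rowMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      matrix(y, d[1], d[2])
    },
    flatten = {
      d <- dim(x); m$inDim <- d
      matrix(x, d[1], prod(d[-1]))
    },
    linear = {
      m$cacheX <- x
      sweep(x %*% t(m$w), 2, m$b, "+")
    },
    dropout = {
      if (training && m$p > 0) {
        mask <- (stats::runif(length(x)) >= m$p) / (1 - m$p)
        dim(mask) <- dim(x)
        m$cacheMask <- mask
        x * mask
      } else {
        m$cacheMask <- NULL
        x
      }
    },
    seq = {
      for (l in m$layers) x <- moduleForward(l, x, training)
      x
    },
    pixelshuffle = pixelShuffleForward(x, m$r),
    bilinearup = {
      d <- dim(x); m$inDim <- d
      A <- bilinearMatrix(m$targetH, d[3])
      B <- bilinearMatrix(m$targetW, d[4])
      m$cacheA <- A; m$cacheB <- B
      y <- array(0, c(d[1], d[2], m$targetH, m$targetW))
      for (n in seq_len(d[1]))
        for (c in seq_len(d[2]))
          y[n, c, , ] <- A %*% x[n, c, , ] %*% t(B)
      y
    },
    residual = forwardResidual(m, x, training),
    groupres = {
      m$cacheX <- x
      x + moduleForward(m$body, x, training)
    },
    res2 = forwardRes2(m, x, training),
    ca = forwardCA(m, x, training),
    pa = forwardPA(m, x, training),
    attnblock = forwardAttnBlock(m, x, training),
    msdc = forwardMSDC(m, x, training),
    msdcrb = {
      m$cacheX <- x
      x + moduleForward(m$body, x, training)
    },
    enhancing = forwardEnhancing(m, x, training),
    stop("unknown module type: ", m$type)
  )
}

# ---- backward ---------------------------------------------------------------

accGrad <- function(m, name, g) {
  cur <- m$grad[[name]]
  m$grad[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

moduleBackward <- function(m, dy) {
  switch(m$type,
    conv = {
      r <- cpp_conv2d_bwd(m$cacheX, m$w, dy, m$stride, m$pad, m$dilation,
                          m$cacheCols)
      m$cacheCols <- NULL
      accGrad(m, "w", r$dw)
      accGrad(m, "b", r$db)
      r$dx
    },
    bn = {
      d <- dim(dy)
      xhat <- m$cacheXhat
      ivar <- m$cacheIvar
      nPer <- d[1] * d[3] * d[4]
      accGrad(m, "gamma", channelSum(dy * xhat))
      accGrad(m, "beta", channelSum(dy))
      dxhat <- dy * bcChannel(m$gamma, d)
      s1 <- channelSum(dxhat)
      s2 <- channelSum(dxhat * xhat)
      (dxhat - bcChannel(s1 / nPer, d) - xhat * bcChannel(s2 / nPer, d)) *
        bcChannel(ivar, d)
    },
    relu = dy * m$cacheMask,
    sigmoid = dy * m$cacheY * (1 - m$cacheY),
    avgpool = cpp_avgpool_bwd(dy, m$k),
    maxpool = cpp_maxpool_bwd(dy, m$cacheArg, as.integer(m$inDim)),
    gap = {
      d <- m$inDim
      g <- as.numeric(dy) / (d[3] * d[4])
      array(rep(g, d[3] * d[4]), dim = d)
    },
    flatten = { dx <- dy; dim(dx) <- m$inDim; dx },
    linear = {
      accGrad(m, "w", t(dy) %*% m$cacheX)
      accGrad(m, "b", colSums(dy))
      dy %*% m$w
    },
    dropout = if (is.null(m$cacheMask)) dy else dy * m$cacheMask,
    seq = {
      for (l in rev(m$layers)) dy <- moduleBackward(l, dy)
      dy
    },
    pixelshuffle = pixelShuffleBackward(dy, m$r),
    bilinearup = {
      d <- m$inDim
      A <- m$cacheA; B <- m$cacheB
      dx <- array(0, d)
      for (n in seq_len(d[1]))
        for (c in seq_len(d[2]))
          dx[n, c, , ] <- t(A) %*% dy[n, c, , ] %*% B
      dx
    },
    residual = backwardResidual(m, dy),
    groupres = dy + moduleBackward(m$body, dy),
    res2 = backwardRes2(m, dy),
    ca = backwardCA(m, dy),
    pa = backwardPA(m, dy),
    attnblock = backwardAttnBlock(m, dy),
    msdc = backwardMSDC(m, dy),
    msdcrb = dy + moduleBackward(m$body, dy),
    enhancing = backwardEnhancing(m, dy),
    stop("unknown module type: ", m$type)
  )
}

# ---- parameter walk / optimiser --------------------------------------------

moduleChildren <- function(m) {
  switch(m$type,
    seq = m$layers,
    residual = c(list(m$body), if (!is.null(m$shortcut)) list(m$shortcut)),
    groupres = list(m$body),
    msdcrb = list(m$body),
    res2 = c(list(m$conv1, m$bn1), m$convs, m$bns, list(m$conv3, m$bn3),
             if (!is.null(m$shortcut)) list(m$shortcut)),
    ca = list(m$fc1, m$fc2),
    pa = list(m$conv1, m$conv2),
    attnblock = list(m$c1, m$c2, m$ca, m$pa),
    msdc = list(m$d1, m$d3, m$d5, m$f13, m$f35, m$fout),
    enhancing = c(list(m$c1, m$c2), m$reducers, m$ups, m$pools, list(m$fuse)),
    list()
  )
}

collectParamModules <- function(m) {
  out <- list()
  walk <- function(mm) {
    if (length(mm$params) > 0) out[[length(out) + 1L]] <<- mm
    for (ch in moduleChildren(mm)) walk(ch)
  }
  walk(m)
  out
}

zeroGrads <- function(mods) {
  for (m in mods) m$grad <- list()
  invisible(NULL)
}

adamStep <- function(mods, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (m in mods) {
    if (is.null(m$opt)) m$opt <- list()
    for (p in m$params) {
      g <- m$grad[[p]]
      if (is.null(g)) next
      st <- m$opt[[p]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      m$opt[[p]] <- st
      m[[p]] <- m[[p]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(NULL)
}

# assign hierarchical names to parameter-bearing modules (for checkpoints)
nameModules <- function(m, prefix = "net") {
  walk <- function(mm, pref) {
    mm$name <- pref
    ch <- moduleChildren(mm)
    if (length(ch) > 0) {
      nms <- names(ch)
      for (i in seq_along(ch)) {
        tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else
          paste0(ch[[i]]$type, i)
        walk(ch[[i]], paste(pref, tag, sep = "."))
      }
    }
  }
  walk(m, prefix)
  invisible(m)
}

namedParamList <- function(m) {
  out <- list()
  for (mm in collectParamModules(m)) {
    nm <- if (is.null(mm$name)) mm$type else mm$name
    for (p in mm$params) out[[paste(nm, p, sep = ".")]] <- mm[[p]]
    if (mm$type == "bn") {
      out[[paste(nm, "runMean", sep = ".")]] <- mm$runMean
      out[[paste(nm, "runVar", sep = ".")]] <- mm$runVar
    }
  }
  out
}

setNamedParams <- function(m, values, strict = TRUE) {
  seen <- character(0)
  for (mm in collectParamModules(m)) {
    nm <- if (is.null(mm$name)) mm$type else mm$name
    slots <- mm$params
    if (mm$type == "bn") slots <- c(slots, "runMean", "runVar")
    for (p in slots) {
      key <- paste(nm, p, sep = ".")
      seen <- c(seen, key)
      if (!key %in% names(values)) {
        if (strict) stop("checkpoint is missing tensor '", key, "'")
        next
      }
      v <- values[[key]]
      cur <- mm[[p]]
      if (!identical(dim(v), dim(cur)) || length(v) != length(cur))
        stop("checkpoint tensor '", key, "' has shape [",
             paste(if (is.null(dim(v))) length(v) else dim(v), collapse = "x"),
             "] but the model expects [",
             paste(if (is.null(dim(cur))) length(cur) else dim(cur), collapse = "x"), "]")
      mm[[p]] <- v
    }
  }
  invisible(seen)
}
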