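# Shared helpers: access to engine internals, a brute-force convolution
# oracle, and a central-difference gradient checker.

df <- asNamespace("duofreq")

# direct sliding-window convolution by nested loops (the independent oracle)
bruteForceConv <- function(x, w, b, stride = 1, pad = 1, dil = 1) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Co <- dim(w)[1]; K <- dim(w)[3]
  OH <- (H + 2 * pad - dil * (K - 1) - 1) %/% stride + 1
  OW <- (W + 2 * pad - dil * (K - 1) - 1) %/% stride + 1
  y <- array(0, c(N, Co, OH, OW))
  for (n in 1:N) for (co in 1:Co) for (oh in 1:OH) for (ow in 1:OW) {
    s <- b[co]
    for (ci in 1:C) for (kh in 1:K) for (kw in 1:K) {
      ih <- (oh - 1) * stride - pad + (kh - 1) * dil + 1
      iw <- (ow - 1) * stride - pad + (kw - 1) * dil + 1
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        s <- s + x[n, ci, ih, iw] * w[co, ci, kh, kw]
    }
    y[n, co, oh, ow] <- s
  }
  y
}

numericGradient <- function(f, z, idx = seq_len(min(length(z), 25)), eps = 1e-6) {
  vapply(idx, function(i) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    (f(zp) - f(zm)) / (2 * eps)
  }, numeric(1))
}

# set every parameter tensor of a module tree to zero
zeroAllParams <- function(module) {
  for (m in df$collectParamModules(module))
    for (p in m$params) if (p != "gamma") m[[p]] <- m[[p]] * 0
  invisible(module)
}

randomImageTensor <- function(n, c, h, w, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n * c * h * w), c(n, c, h, w))
}

tinyLFConfig <- function() MSDCConfig(channels = 8, nGroups = 1, nBlocksPerGroup = 1)
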