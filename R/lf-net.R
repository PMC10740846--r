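# Low-frequency branch: full-resolution feature extraction through
# multi-stream dilated-convolution residual blocks.  No operation in this
# branch changes the spatial resolution.

#' 3x3 dilated convolution preserving spatial size
#'
#' Functional wrapper around the engine's convolution kernel: a 3x3
#' convolution with dilation `r` and zero padding `r`, so output H x W equals
#' input H x W.  `r = 1` is an ordinary 3x3 convolution.
#'
#' @param x input array, dim `(C, H, W)` or `(N, C, H, W)`.
#' @param w weight array, dim `(Cout, Cin, 3, 3)`.
#' @param b bias vector of length `Cout` (default zeros).
#' @param dilation dilation rate, one of 1, 3, 5.
#' @return the convolved array, same spatial size as the input.
#' @export
dilatedConv3x3 <- function(x, w, b = NULL, dilation = 1L) {
  dilation <- as.integer(dilation)
  if (!dilation %in% c(1L, 3L, 5L))
    stop("dilation rate must be one of 1, 3, 5 (got ", dilation, ")")
  if (is.null(b)) b <- numeric(dim(w)[1])
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(1L, dim(x))
  y <- cpp_conv2d_fwd(x, w, b, 1L, dilation, dilation)$y
  if (single) { d <- dim(y); dim(y) <- d[-1] }
  y
}

#' Multi-stream dilated convolution block
#'
#' Three parallel 3x3 convolutions with dilation rates 1, 3 and 5 (each C
#' channels, the rate-3 stream computed once and shared); adjacent streams
#' are concatenated and fused by a 1x1 convolution with ReLU
#' (`relu(conv1x1(cat(D1, D3)))` and likewise for `(D3, D5)`), and a final
#' 1x1 convolution on the concatenated pair restores C output channels.
#' Spatial size is preserved; the composite receptive field is 11x11.
#'
#' @param C channel count (input and output).
#' @return a module usable with [forwardPass()].
#' @export
msdcBlock <- function(C) nnMSDC(as.integer(C))

#' Multi-stream dilated convolution residual block
#'
#' Adds the block input to the [msdcBlock()] output: `y = x + MSDC(x)`.
#' With all weights zero the block is exactly the identity.
#'
#' @inheritParams msdcBlock
#' @return a module usable with [forwardPass()].
#' @export
msdcResidualBlock <- function(C) nnMSDCRB(as.integer(C))

#' Build the low-frequency branch
#'
#' A head 3x3 convolution lifts the 3-channel image into `cfg@channels`
#' feature channels ("image space into feature space"), `nGroups` groups of
#' `nBlocksPerGroup` residual blocks follow (each group optionally wrapped in
#' its own residual connection), and a tail 3x3 convolution closes the
#' branch; global average pooling turns the full-resolution map into a
#' feature vector.  The branch never downsamples.
#'
#' @param cfg an [MSDCConfig-class] object.
#' @param includePool if `FALSE`, return the full-resolution feature map
#'   instead of pooled features.
#' @return a module usable with [forwardPass()]; `outChannels` gives the
#'   feature width.
#' @examples
#' lf <- lfBranch(MSDCConfig(channels = 8, nGroups = 1, nBlocksPerGroup = 1))
#' length(forwardPass(lf, array(0, c(3, 32, 32))))
#' @export
lfBranch <- function(cfg = MSDCConfig(), includePool = TRUE) {
  stopifnot(is(cfg, "MSDCConfig"))
  validObject(cfg)
  C <- cfg@channels
  layers <- list(nnConv(3L, C, 3))
  for (g in seq_len(cfg@nGroups)) {
    blocks <- lapply(seq_len(cfg@nBlocksPerGroup), function(i) nnMSDCRB(C))
    grp <- if (cfg@groupResidual) newModule("groupres", body = nnSeq(blocks))
           else nnSeq(blocks)
    layers <- c(layers, list(grp))
  }
  layers <- c(layers, list(nnConv(C, C, 3)))
  if (includePool) layers <- c(layers, list(nnGlobalAvgPool()))
  m <- nnSeq(layers)
  m$outChannels <- C
  nameModules(m, "lf")
  m
}

#' Count of residual blocks instantiated by a configuration
#' @param cfg an [MSDCConfig-class] object.
#' @return integer, `nGroups * nBlocksPerGroup`.
#' @export
msdcBlockCount <- function(cfg) cfg@nGroups * cfg@nBlocksPerGroup

#' Closed-form parameter count of the low-frequency branch
#'
#' Each residual block holds three dilated 3x3 convolutions (C -> C) and
#' three 1x1 fusions (2C -> C), all with biases; the head and tail are plain
#' 3x3 convolutions.  Parameters grow linearly in `nGroups *
#' nBlocksPerGroup`.
#'
#' @param cfg an [MSDCConfig-class] object.
#' @return the exact number of scalar parameters of [lfBranch()].
#' @export
lfParameterCount <- function(cfg) {
  C <- as.numeric(cfg@channels)
  perBlock <- 3 * (C * C * 9 + C) + 3 * (2 * C * C + C)
  head <- 3 * C * 9 + C
  tail <- C * C * 9 + C
  head + tail + msdcBlockCount(cfg) * perBlock
}
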