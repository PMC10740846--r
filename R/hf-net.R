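# High-frequency branch: truncated backbone -> feature attention ->
# sub-pixel upsampling -> multi-scale enhancing block.

#' Channel attention module
#'
#' Gates each channel by a weight in (0, 1) computed from the globally
#' average-pooled features through a two-layer bottleneck (ReLU between,
#' sigmoid after).  With all gate-subnetwork weights zero the gate is
#' sigmoid(0) = 0.5 everywhere, so the output is half the input.
#'
#' @param C number of channels.
#' @param reduction bottleneck reduction factor of the gate subnetwork.
#' @return a module usable with [forwardPass()].
#' @export
channelAttention <- function(C, reduction = 4L) {
  nnChannelAttention(as.integer(C), as.integer(reduction))
}

#' Pixel attention module
#'
#' Gates each spatial position by a single-channel H x W map in (0, 1),
#' computed by two 1x1 convolutions (ReLU between, sigmoid after) and
#' broadcast over channels.
#'
#' @inheritParams channelAttention
#' @return a module usable with [forwardPass()].
#' @export
pixelAttention <- function(C, reduction = 4L) {
  nnPixelAttention(as.integer(C), as.integer(reduction))
}

#' Feature attention block
#'
#' A local residual unit `y = x + PA(CA(conv(relu(conv(x)))))`: two 3x3
#' convolutions feed channel attention then pixel attention, and the result
#' is added back onto the input.  With all convolution weights zero the block
#' is exactly the identity.
#'
#' @param C number of channels.
#' @return a module usable with [forwardPass()].
#' @export
attentionBlock <- function(C) nnAttentionBlock(as.integer(C))

#' Sub-pixel (pixel-shuffle) upsampling
#'
#' Rearranges `r^2` channel groups into an `r`-times larger spatial grid:
#' channels `C -> C / r^2`, space `H x W -> rH x rW`.  The operation is a
#' pure permutation of values (no arithmetic), so it is exactly invertible.
#'
#' @param x feature map, dim `(C, H, W)` or `(N, C, H, W)`; `C` must be
#'   divisible by `r^2`.
#' @param r upsampling factor.
#' @return the shuffled array.
#' @examples
#' x <- array(1:16, c(4, 2, 2))
#' sort(subpixelUpsample(x, 2)) # same multiset of values
#' @export
subpixelUpsample <- function(x, r) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(1L, dim(x))
  y <- pixelShuffleForward(x, as.integer(r))
  if (single) { d <- dim(y); dim(y) <- d[-1] }
  y
}

#' Inverse of [subpixelUpsample()] (space-to-channel)
#' @inheritParams subpixelUpsample
#' @return the inverse-shuffled array.
#' @export
spaceToChannel <- function(x, r) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(1L, dim(x))
  y <- pixelShuffleBackward(x, as.integer(r))
  if (single) { d <- dim(y); dim(y) <- d[-1] }
  y
}

#' Multi-scale enhancing block
#'
#' Two front-end 3x3 convolutions, then an average-pooling pyramid at the
#' given kernel sizes (kernel = stride, non-overlapping); each pooled map is
#' reduced to `C/4` channels by a 1x1 convolution, bilinearly upsampled back
#' to the input size, concatenated with the front-end output and fused by a
#' final 3x3 convolution.  Output spatial size equals input spatial size.
#'
#' @param C number of channels.
#' @param poolSizes average-pooling kernel sizes; the input must be at least
#'   as large as the largest kernel.
#' @return a module usable with [forwardPass()].
#' @export
enhancingBlock <- function(C, poolSizes = c(4L, 8L, 16L, 32L)) {
  nnEnhancingBlock(as.integer(C), as.integer(poolSizes))
}

#' Build the high-frequency branch
#'
#' Assembles backbone, feature-attention blocks, sub-pixel upsampling and the
#' enhancing block in that order, followed by global average pooling, so the
#' branch maps an image to a feature vector.
#'
#' @param cfg an [HFConfig-class] object.
#' @param includePool if `FALSE`, stop before the global average pool and
#'   return the spatial feature map instead.
#' @return a module usable with [forwardPass()]; its `outChannels` field
#'   gives the feature-vector length.
#' @examples
#' hf <- hfBranch(tinyHFConfig())
#' length(forwardPass(hf, array(0, c(3, 64, 64))))
#' @export
hfBranch <- function(cfg = HFConfig(), includePool = TRUE) {
  stopifnot(is(cfg, "HFConfig"))
  validObject(cfg)
  bb <- buildBackbone(cfg@backbone)
  C <- bb$outChannels
  layers <- list(bb)
  if (cfg@attentionEnabled && cfg@nAttentionBlocks > 0L)
    for (i in seq_len(cfg@nAttentionBlocks))
      layers <- c(layers, list(nnAttentionBlock(C)))
  r <- cfg@upsampleFactor
  if (r > 1L) {
    if (C %% (r * r) != 0L)
      stop("backbone width ", C, " is not divisible by upsampleFactor^2")
    layers <- c(layers, list(nnPixelShuffle(r)))
    C <- C %/% (r * r)
  }
  layers <- c(layers, list(nnEnhancingBlock(C, cfg@enhancingPoolSizes)))
  if (includePool) layers <- c(layers, list(nnGlobalAvgPool()))
  m <- nnSeq(layers)
  m$outChannels <- C
  nameModules(m, "hf")
  m
}

#' Tiny high-frequency configuration for CPU-scale experiments
#'
#' Tiny backbone (output stride 16), two attention blocks, 2x sub-pixel
#' upsampling and an enhancing pyramid scaled down to `c(1, 2, 4, 8)` so it
#' fits the small feature maps.
#'
#' @param family backbone family for the tiny backbone.
#' @return an [HFConfig-class] object.
#' @export
tinyHFConfig <- function(family = "resnet") {
  HFConfig(backbone = BackboneConfig(family, "tiny"),
           nAttentionBlocks = 2L, upsampleFactor = 2L,
           enhancingPoolSizes = c(1L, 2L, 4L, 8L))
}
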