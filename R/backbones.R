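# Residual backbones for the high-frequency branch.  All variants drop the
# classifier head and return a spatial feature map (output stride 32 for the
# standard depths, 16 for the tiny test variant).

#' Run a module (or assembled network) forward
#'
#' Applies a layer, block or branch built by the package's constructors to a
#' feature map.  Feature maps are arrays with dim `(C, H, W)` for a single
#' sample or `(N, C, H, W)` for a batch; a single sample is wrapped and
#' unwrapped transparently.
#'
#' @param module a module created by e.g. [residualBlock()], [msdcBlock()],
#'   [buildBackbone()], [hfBranch()], or a [DualFreqNet-class] network.
#' @param x input array.
#' @param training logical; enables batch-statistics and dropout behaviour.
#' @return the module's output (array, or matrix of pooled features/logits).
#' @examples
#' blk <- residualBlock(4, 4)
#' y <- forwardPass(blk, array(rnorm(4 * 8 * 8), c(4, 8, 8)))
#' dim(y)
#' @export
forwardPass <- function(module, x, training = FALSE) {
  if (is(module, "DualFreqNet")) return(networkForward(module, x, training)$logits)
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(1L, dim(x))
  y <- moduleForward(module, x, training)
  if (single && length(dim(y)) == 4L && dim(y)[1] == 1L) {
    d <- dim(y); dim(y) <- d[-1]
  }
  y
}

#' Basic residual block
#'
#' Two 3x3 convolutions (each followed by batch normalisation) wrapped in a
#' skip connection: the shortcut is the identity when input and output shapes
#' match and a 1x1 projection (with batch norm) otherwise.  A stride-2 block
#' halves the spatial dimensions.
#'
#' @param inC,outC input / output channel counts.
#' @param stride stride of the first convolution.
#' @return a module usable with [forwardPass()].
#' @export
residualBlock <- function(inC, outC, stride = 1L) {
  makeBasicBlock(as.integer(inC), as.integer(outC), as.integer(stride))
}

#' Multi-scale (hierarchical) residual bottleneck
#'
#' A bottleneck block whose inner 3x3 convolution is expanded into `scale`
#' hierarchical sub-groups: group 1 passes through unchanged, group 2 is
#' convolved, and each later group is convolved after adding the previous
#' group's output, so the effective receptive field grows with the group
#' index.  With `scale = 1` the block reduces exactly to a standard
#' bottleneck.
#'
#' @param inC input channels.
#' @param planes inner width (must be divisible by `scale`).
#' @param stride stride of the grouped convolutions.
#' @param scale number of sub-groups.
#' @return a module usable with [forwardPass()].
#' @export
res2Block <- function(inC, planes, stride = 1L, scale = 4L) {
  nnRes2Block(as.integer(inC), as.integer(planes), as.integer(stride),
              as.integer(scale))
}

bottleneckBlock <- function(inC, planes, stride = 1L)
  nnRes2Block(inC, planes, stride, scale = 1L)

resnetStage <- function(makeBlock, inC, outC, nBlocks, stride) {
  blocks <- list(makeBlock(inC, stride))
  for (i in seq_len(nBlocks - 1L)) blocks[[i + 1L]] <- makeBlock(outC, 1L)
  nnSeq(blocks)
}

#' Build a truncated residual backbone
#'
#' Maps a 3-channel image to a spatial feature map with no classifier head.
#' Standard depths (`"18"`, `"50"`, `"101"`) have output stride 32 (a
#' 3x256x256 input yields 512x8x8 for depth 18 and 2048x8x8 for the
#' bottleneck depths).  The `"tiny"` variant (2 stages, widths 16/32,
#' output stride 16) exists for fast CPU experiments.
#'
#' @param cfg a [BackboneConfig-class] object.
#' @return a module (use [forwardPass()]); its `outChannels` field gives the
#'   feature width.
#' @examples
#' bb <- buildBackbone(BackboneConfig("resnet", "tiny"))
#' dim(forwardPass(bb, array(0, c(3, 64, 64))))   # 32 x 4 x 4
#' @export
buildBackbone <- function(cfg) {
  stopifnot(is(cfg, "BackboneConfig"))
  validObject(cfg)
  s <- cfg@res2Scale
  if (cfg@depth == "tiny") {
    m <- nnSeq(
      nnConv(3L, 16L, 3, stride = 2L), nnBatchNorm(16L), nnReLU(), nnMaxPool(),
      resnetStage(function(ic, st) {
        if (cfg@family == "res2net") nnRes2Block(ic, 4L, st, scale = min(s, 4L))
        else makeBasicBlock(ic, 16L, st)
      }, 16L, 16L, 1L, 2L),
      resnetStage(function(ic, st) {
        if (cfg@family == "res2net") nnRes2Block(ic, 8L, st, scale = min(s, 4L))
        else makeBasicBlock(ic, 32L, st)
      }, 16L, 32L, 1L, 2L))
    m$outChannels <- 32L
    nameModules(m, "backbone")
    return(m)
  }
  stem <- list(nnConv(3L, 64L, 7, stride = 2L, pad = 3L), nnBatchNorm(64L),
               nnReLU(), nnMaxPool())
  if (cfg@depth == "18") {
    if (cfg@family != "resnet") stop("unknown depth for this family: 18")
    widths <- c(64L, 128L, 256L, 512L)
    counts <- c(2L, 2L, 2L, 2L)
    mk <- function(w) function(ic, st) makeBasicBlock(ic, w, st)
    outC <- 512L
  } else {
    counts <- switch(cfg@depth, "50" = c(3L, 4L, 6L, 3L),
                     "101" = c(3L, 4L, 23L, 3L),
                     stop("unknown backbone depth: ", cfg@depth))
    widths <- c(256L, 512L, 1024L, 2048L)
    planes <- c(64L, 128L, 256L, 512L)
    scl <- if (cfg@family == "res2net") s else 1L
    mk <- function(w) {
      p <- planes[match(w, widths)]
      function(ic, st) nnRes2Block(ic, p, st, scale = scl)
    }
    outC <- 2048L
  }
  stages <- list()
  inC <- 64L
  strides <- c(1L, 2L, 2L, 2L)
  for (i in 1:4) {
    stages[[i]] <- resnetStage(mk(widths[i]), inC, widths[i], counts[i], strides[i])
    inC <- widths[i]
  }
  m <- nnSeq(c(stem, stages))
  m$outChannels <- outC
  nameModules(m, "backbone")
  m
}

#' Save model or module weights
#'
#' Serialises every named parameter tensor (and batch-norm running statistics)
#' to an RDS checkpoint.
#'
#' @param model a [DualFreqNet-class] network or a single module.
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveModelWeights <- function(model, path) {
  values <- if (is(model, "DualFreqNet")) {
    v <- list()
    for (part in modelParts(model)) v <- c(v, namedParamList(part))
    v
  } else namedParamList(model)
  saveRDS(values, path)
  invisible(path)
}

#' Load external weights into a feature extractor
#'
#' Reads a checkpoint written by [saveModelWeights()] and copies every tensor
#' into the module, with strict name and shape checking.  Tensors in the
#' checkpoint that belong to a classifier head (names starting with `"head"`)
#' are ignored, so backbone checkpoints can be reused across tasks.  Training
#' works from random initialisation when no checkpoint is supplied; loading is
#' an optional warm start.
#'
#' @param extractor a module built by e.g. [buildBackbone()].
#' @param checkpointPath path to an RDS checkpoint.
#' @return the extractor, invisibly (weights are replaced in place).
#' @export
loadExternalWeights <- function(extractor, checkpointPath) {
  if (!file.exists(checkpointPath))
    stop("checkpoint file not found: ", checkpointPath)
  values <- readRDS(checkpointPath)
  values <- values[!startsWith(names(values), "head")]
  setNamedParams(extractor, values, strict = TRUE)
  invisible(extractor)
}
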