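#' @import methods
NULL

# ---- synthetic data ---------------------------------------------------------

#' Per-class specification for the synthetic image generator
#'
#' Describes how one class of synthetic images is drawn.  The class signal is
#' split between a low-frequency component (a Gaussian-blurred elliptical blob
#' whose size, eccentricity and position carry shape information) and a
#' high-frequency component (an oriented band-limited grating whose spatial
#' frequency and orientation carry texture information).  The mixing weight
#' `hfWeight` moves the class signal continuously between the two regimes.
#'
#' @slot classId integer class label in `0..3`.
#' @slot blobRadius mean effective radius of the blob in pixels (the ellipse
#'   keeps area `pi * blobRadius^2` at every eccentricity, so radius and
#'   eccentricity are independent knobs).
#' @slot blobRadiusSpread standard deviation of the per-sample radius draw.
#' @slot blobEccentricity eccentricity in `[0, 1)`.
#' @slot blobCenterJitter standard deviation (pixels) of the blob centre.
#' @slot textureFreq grating frequency in cycles/pixel, in `(0, 0.5]`.
#' @slot textureOrientation grating orientation in degrees, in `[0, 180)`.
#' @slot hfWeight mixing weight of the texture field, in `[0, 1]`.
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise.
#' @exportClass SyntheticClassSpec
setClass("SyntheticClassSpec",
  representation(classId = "integer", blobRadius = "numeric",
                 blobRadiusSpread = "numeric", blobEccentricity = "numeric",
                 blobCenterJitter = "numeric", textureFreq = "numeric",
                 textureOrientation = "numeric", hfWeight = "numeric",
                 noiseSd = "numeric"))

setValidity("SyntheticClassSpec", function(object) {
  msg <- character(0)
  if (object@classId < 0L || object@classId > 3L)
    msg <- c(msg, "classId must be in 0..3")
  if (object@blobRadius <= 0) msg <- c(msg, "blobRadius must be positive")
  if (object@blobEccentricity < 0 || object@blobEccentricity >= 1)
    msg <- c(msg, "blobEccentricity must be in [0, 1)")
  if (object@textureFreq <= 0 || object@textureFreq > 0.5)
    msg <- c(msg, "textureFreq must lie in (0, 0.5] cycles/pixel (Nyquist)")
  if (object@hfWeight < 0 || object@hfWeight > 1)
    msg <- c(msg, "hfWeight must be in [0, 1]")
  if (object@blobCenterJitter < 0) msg <- c(msg, "blobCenterJitter must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticClassSpec-class
#' @param classId,blobRadius,blobRadiusSpread,blobEccentricity,blobCenterJitter
#'   see the corresponding slots.
#' @param textureFreq,textureOrientation,hfWeight,noiseSd see the slots.
#' @return a `SyntheticClassSpec` object.
#' @examples
#' SyntheticClassSpec(0, blobRadius = 10, textureFreq = 0.3)
#' @export
SyntheticClassSpec <- function(classId, blobRadius = 9, blobRadiusSpread = 1,
                               blobEccentricity = 0.3, blobCenterJitter = 3,
                               textureFreq = 0.3, textureOrientation = 0,
                               hfWeight = 0.5, noiseSd = 0.05) {
  new("SyntheticClassSpec", classId = as.integer(classId),
      blobRadius = blobRadius, blobRadiusSpread = blobRadiusSpread,
      blobEccentricity = blobEccentricity, blobCenterJitter = blobCenterJitter,
      textureFreq = textureFreq, textureOrientation = textureOrientation %% 180,
      hfWeight = hfWeight, noiseSd = noiseSd)
}

setMethod("show", "SyntheticClassSpec", function(object) {
  cat(sprintf(
    "SyntheticClassSpec(class %d): blob r=%.1f (ecc %.2f, jitter %.1f), texture %.2f c/p @ %.0f deg, hfWeight %.2f, noise %.3f\n",
    object@classId, object@blobRadius, object@blobEccentricity,
    object@blobCenterJitter, object@textureFreq, object@textureOrientation,
    object@hfWeight, object@noiseSd))
})

#' Manifest of a generated synthetic dataset
#'
#' @slot dir directory the PNG files were written to.
#' @slot imageSize image side length in pixels.
#' @slot masterSeed the master seed every per-sample seed derives from.
#' @slot samples data.frame with columns `path`, `class_id`, `seed`.
#' @exportClass SyntheticDatasetManifest
setClass("SyntheticDatasetManifest",
  representation(dir = "character", imageSize = "integer",
                 masterSeed = "integer", samples = "data.frame"))

setValidity("SyntheticDatasetManifest", function(object) {
  need <- c("path", "class_id", "seed")
  if (!all(need %in% names(object@samples)))
    return("samples must have columns path, class_id, seed")
  TRUE
})

setMethod("show", "SyntheticDatasetManifest", function(object) {
  cat(sprintf("SyntheticDatasetManifest: %d images (%dx%d), %d classes, master seed %d\n",
              nrow(object@samples), object@imageSize, object@imageSize,
              length(unique(object@samples$class_id)), object@masterSeed))
})

# ---- preprocessing ----------------------------------------------------------

#' Stratified split specification
#'
#' Train/validation/test fractions with the rounding rule used to turn them
#' into per-class counts: train and validation counts are rounded half-up,
#' the remainder goes to test.
#'
#' @slot fractions numeric length-3 vector (train, validation, test).
#' @slot rounding rounding rule identifier (only `"half-up"` is defined).
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(fractions = "numeric", rounding = "character"))

setValidity("SplitSpec", function(object) {
  if (length(object@fractions) != 3L) return("fractions must have length 3")
  if (abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
  if (any(object@fractions < 0)) return("fractions must be non-negative")
  TRUE
})

#' @rdname SplitSpec-class
#' @param fractions train/validation/test fractions summing to 1.
#' @return a `SplitSpec` object.
#' @export
SplitSpec <- function(fractions = c(0.70, 0.20, 0.10)) {
  new("SplitSpec", fractions = fractions, rounding = "half-up")
}

#' Augmentation plan
#'
#' `"whole"` mode emits one rotated copy per angle (rotation angles restricted
#' to 15-45 degrees so the subject stays in frame); `"roi"` mode emits a
#' horizontally and a vertically flipped copy.
#'
#' @slot mode `"whole"` or `"roi"`.
#' @slot rotationAngles rotation angles in degrees.
#' @slot flips flip axes used in roi mode.
#' @slot targetSize side length images are resized to before augmentation.
#' @exportClass AugmentationPlan
setClass("AugmentationPlan",
  representation(mode = "character", rotationAngles = "numeric",
                 flips = "character", targetSize = "integer"))

setValidity("AugmentationPlan", function(object) {
  if (!object@mode %in% c("whole", "roi")) return("mode must be 'whole' or 'roi'")
  if (object@mode == "whole" && length(object@rotationAngles) == 0L)
    return("whole mode requires a non-empty set of rotation angles")
  if (length(object@rotationAngles) &&
      (min(object@rotationAngles) < 15 || max(object@rotationAngles) > 45))
    return("rotation angles must lie within [15, 45] degrees")
  TRUE
})

#' @rdname AugmentationPlan-class
#' @param mode `"whole"` or `"roi"`.
#' @param rotationAngles rotation angles (degrees) for whole mode.
#' @param flips flip axes for roi mode.
#' @param targetSize target image side length.
#' @return an `AugmentationPlan` object.
#' @export
AugmentationPlan <- function(mode = c("whole", "roi"),
                             rotationAngles = c(15, 25, 35, 45),
                             flips = c("horizontal", "vertical"),
                             targetSize = 256L) {
  mode <- match.arg(mode)
  new("AugmentationPlan", mode = mode, rotationAngles = rotationAngles,
      flips = flips, targetSize = as.integer(targetSize))
}

# ---- architecture configs ---------------------------------------------------

#' Backbone configuration for the high-frequency branch
#'
#' @slot family `"resnet"` or `"res2net"`.
#' @slot depth `"18"`, `"50"`, `"101"` or `"tiny"` (a 2-stage variant with
#'   widths 16/32 for fast CPU work).
#' @slot res2Scale number of hierarchical sub-groups inside the multi-scale
#'   bottleneck (res2net family only).
#' @slot truncateHead always `TRUE`: the classifier head is discarded and the
#'   backbone is used as a feature extractor.
#' @exportClass BackboneConfig
setClass("BackboneConfig",
  representation(family = "character", depth = "character",
                 res2Scale = "integer", truncateHead = "logical"))

setValidity("BackboneConfig", function(object) {
  if (!object@family %in% c("resnet", "res2net"))
    return("family must be 'resnet' or 'res2net'")
  if (!object@depth %in% c("18", "50", "101", "tiny"))
    return("depth must be one of '18', '50', '101', 'tiny'")
  if (object@family == "res2net" && object@depth == "18")
    return("the multi-scale bottleneck family has no depth-18 variant")
  if (object@res2Scale < 1L) return("res2Scale must be >= 1")
  TRUE
})

#' @rdname BackboneConfig-class
#' @param family,depth,res2Scale see the slots.
#' @return a `BackboneConfig` object.
#' @examples
#' BackboneConfig("resnet", "18")
#' BackboneConfig("res2net", "50", res2Scale = 4)
#' @export
BackboneConfig <- function(family = c("resnet", "res2net"), depth = "tiny",
                           res2Scale = 4L) {
  family <- match.arg(family)
  new("BackboneConfig", family = family, depth = as.character(depth),
      res2Scale = as.integer(res2Scale), truncateHead = TRUE)
}

#' High-frequency branch configuration
#'
#' Pipeline order: truncated backbone, `nAttentionBlocks` feature-attention
#' blocks, sub-pixel (pixel-shuffle) upsampling by `upsampleFactor`, then the
#' multi-scale enhancing block with average-pooling kernels
#' `enhancingPoolSizes`.
#'
#' @slot backbone a [BackboneConfig-class] object.
#' @slot nAttentionBlocks number of feature-attention blocks.
#' @slot upsampleFactor sub-pixel upsampling factor (power of 2).
#' @slot enhancingPoolSizes average-pooling kernel sizes of the pyramid.
#' @slot attentionEnabled set `FALSE` to bypass the attention blocks.
#' @exportClass HFConfig
setClass("HFConfig",
  representation(backbone = "BackboneConfig", nAttentionBlocks = "integer",
                 upsampleFactor = "integer", enhancingPoolSizes = "integer",
                 attentionEnabled = "logical"))

setValidity("HFConfig", function(object) {
  f <- object@upsampleFactor
  if (f < 1L || bitwAnd(f, f - 1L) != 0L)
    return("upsampleFactor must be a power of 2")
  if (object@nAttentionBlocks < 0L) return("nAttentionBlocks must be >= 0")
  TRUE
})

#' @rdname HFConfig-class
#' @param backbone,nAttentionBlocks,upsampleFactor,enhancingPoolSizes,attentionEnabled
#'   see the slots.
#' @return an `HFConfig` object.
#' @export
HFConfig <- function(backbone = BackboneConfig(), nAttentionBlocks = 2L,
                     upsampleFactor = 2L,
                     enhancingPoolSizes = c(4L, 8L, 16L, 32L),
                     attentionEnabled = TRUE) {
  new("HFConfig", backbone = backbone,
      nAttentionBlocks = as.integer(nAttentionBlocks),
      upsampleFactor = as.integer(upsampleFactor),
      enhancingPoolSizes = as.integer(enhancingPoolSizes),
      attentionEnabled = attentionEnabled)
}

#' Low-frequency branch configuration
#'
#' The branch keeps full input resolution throughout: a head 3x3 convolution
#' lifts the image into `channels` feature channels, `nGroups` groups of
#' `nBlocksPerGroup` multi-stream dilated-convolution residual blocks follow
#' (each group optionally wrapped in its own residual connection), and a tail
#' 3x3 convolution closes the branch.
#'
#' @slot dilations dilation rates of the three streams; fixed at `c(1, 3, 5)`.
#' @slot channels feature width `C`.
#' @slot nGroups number of block groups.
#' @slot nBlocksPerGroup blocks per group.
#' @slot groupResidual whether each group carries a group-level residual
#'   connection.
#' @exportClass MSDCConfig
setClass("MSDCConfig",
  representation(dilations = "integer", channels = "integer",
                 nGroups = "integer", nBlocksPerGroup = "integer",
                 groupResidual = "logical"))

setValidity("MSDCConfig", function(object) {
  if (!identical(object@dilations, c(1L, 3L, 5L)))
    return("dilations must be exactly c(1, 3, 5)")
  if (object@nGroups < 1L || object@nBlocksPerGroup < 1L)
    return("nGroups and nBlocksPerGroup must be >= 1")
  if (object@channels < 1L) return("channels must be >= 1")
  TRUE
})

#' @rdname MSDCConfig-class
#' @param channels,nGroups,nBlocksPerGroup,groupResidual see the slots.
#' @return an `MSDCConfig` object.
#' @examples
#' MSDCConfig()                      # the (3, 3) default
#' MSDCConfig(channels = 16, nGroups = 1, nBlocksPerGroup = 1)  # tiny
#' @export
MSDCConfig <- function(channels = 64L, nGroups = 3L, nBlocksPerGroup = 3L,
                       groupResidual = TRUE) {
  new("MSDCConfig", dilations = c(1L, 3L, 5L), channels = as.integer(channels),
      nGroups = as.integer(nGroups), nBlocksPerGroup = as.integer(nBlocksPerGroup),
      groupResidual = groupResidual)
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the training protocol the architecture was designed with:
#' batch size 8, 300 epochs, Adam with learning rate 1e-4 and
#' `beta1 = 0.9`, `beta2 = 0.999`, dropout 0.3 in the fusion head, random
#' seed 3407, and learning curves logged every 15 epochs.
#'
#' @slot batchSize mini-batch size.
#' @slot epochs number of training epochs.
#' @slot lr Adam learning rate.
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot dropout dropout probability of the fusion head.
#' @slot seed RNG seed for shuffling, dropout and weight initialisation.
#' @slot logEvery learning-curve cadence in epochs.
#' @slot imageSize expected input side length.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer", lr = "numeric",
                 beta1 = "numeric", beta2 = "numeric", dropout = "numeric",
                 seed = "integer", logEvery = "integer", imageSize = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  TRUE
})

#' @rdname TrainConfig-class
#' @param batchSize,epochs,lr,beta1,beta2,dropout,seed,logEvery,imageSize
#'   see the slots.
#' @return a `TrainConfig` object.
#' @export
TrainConfig <- function(batchSize = 8L, epochs = 300L, lr = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, dropout = 0.30,
                        seed = 3407L, logEvery = 15L, imageSize = 256L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), lr = lr, beta1 = beta1, beta2 = beta2,
      dropout = dropout, seed = as.integer(seed),
      logEvery = as.integer(logEvery), imageSize = as.integer(imageSize))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: batch %d, %d epochs, Adam(lr=%g, b1=%g, b2=%g), dropout %.2f, seed %d, log every %d epochs\n",
    object@batchSize, object@epochs, object@lr, object@beta1, object@beta2,
    object@dropout, object@seed, object@logEvery))
})

# ---- outputs ----------------------------------------------------------------

#' Classifier output: logits, probabilities and predicted classes
#'
#' @slot logits numeric matrix (samples x classes).
#' @slot probs numeric matrix of per-class probabilities (rows sum to 1).
#' @slot predictedClass integer vector of 0-based predicted class labels.
#' @exportClass ClassifierOutput
setClass("ClassifierOutput",
  representation(logits = "matrix", probs = "matrix",
                 predictedClass = "integer"))

setValidity("ClassifierOutput", function(object) {
  if (!all(abs(rowSums(object@probs) - 1) < 1e-6))
    return("probabilities must sum to 1 per sample")
  if (!identical(unname(apply(object@probs, 1, which.max) - 1L),
                 unname(object@predictedClass)))
    return("predictedClass must be the argmax of the probabilities")
  TRUE
})

setMethod("show", "ClassifierOutput", function(object) {
  cat(sprintf("ClassifierOutput: %d samples, %d classes\n",
              nrow(object@probs), ncol(object@probs)))
})

#' Evaluation report
#'
#' @slot confusion confusion matrix, rows = true class, columns = predicted.
#' @slot accuracy overall accuracy (trace / total).
#' @slot perClass data.frame of one-vs-rest TP/FP/FN/TN, precision, recall and
#'   F1 per class, plus a `degenerate` flag for zero-denominator cells.
#' @slot macro named numeric vector with macro-averaged precision/recall/F1.
#' @slot roc list of per-class data.frames with columns `fpr`, `tpr`.
#' @slot auc named numeric vector of per-class AUCs.
#' @slot microRoc,macroRoc pooled and interpolated average ROC curves.
#' @slot microAuc,macroAuc their AUCs.
#' @slot classNames class names in label order.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 perClass = "data.frame", macro = "numeric", roc = "list",
                 auc = "numeric", microRoc = "data.frame",
                 macroRoc = "data.frame", microAuc = "numeric",
                 macroAuc = "numeric", classNames = "character"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d samples, %d classes\n",
              sum(object@confusion), nrow(object@confusion)))
  cat(sprintf("  accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              object@accuracy, object@macro["precision"],
              object@macro["recall"], object@macro["f1"]))
  if (length(object@auc))
    cat("  AUC:", paste(sprintf("%s %.3f", names(object@auc), object@auc),
                        collapse = ", "),
        sprintf("| micro %.3f macro %.3f\n", object@microAuc, object@macroAuc))
})

#' Dataset manifest for directory-per-class image trees
#'
#' @slot root dataset root directory.
#' @slot classes class names (subdirectory names), label order.
#' @slot files data.frame with columns `path`, `class`, `label` (0-based).
#' @slot splits named list of integer index vectors (`train`, `val`, `test`),
#'   possibly empty before splitting.
#' @exportClass DatasetManifest
setClass("DatasetManifest",
  representation(root = "character", classes = "character",
                 files = "data.frame", splits = "list"))

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d images, %d classes (%s)\n",
              nrow(object@files), length(object@classes),
              paste(object@classes, collapse = ", ")))
  if (length(object@splits))
    cat("  splits:", paste(sprintf("%s=%d", names(object@splits),
                                   lengths(object@splits)), collapse = ", "), "\n")
})

# ---- the assembled network --------------------------------------------------

#' The dual-branch frequency-guided classification network
#'
#' Holds the high-frequency branch, the low-frequency branch and the fusion
#' head as mutable module trees, together with the configuration they were
#' built from.  `mode` selects the ablation variant: `"fused"` uses both
#' branches, `"hf_only"` / `"lf_only"` route a single branch into the same
#' fusion head.
#'
#' @slot mode `"fused"`, `"hf_only"` or `"lf_only"`.
#' @slot nClasses number of output classes (2, 3 or 4).
#' @slot hfBranch,lfBranch,head module environments (engine internals).
#' @slot hfConfig,lfConfig the branch configurations.
#' @slot binarySigmoid if `TRUE` and `nClasses == 2`, the head is read out
#'   through a sigmoid on a single logit rather than a 2-way softmax.
#' @exportClass DualFreqNet
setClass("DualFreqNet",
  representation(mode = "character", nClasses = "integer", hfBranch = "ANY",
                 lfBranch = "ANY", head = "ANY", hfConfig = "ANY",
                 lfConfig = "ANY", binarySigmoid = "logical"))

setValidity("DualFreqNet", function(object) {
  if (!object@mode %in% c("fused", "hf_only", "lf_only"))
    return("mode must be 'fused', 'hf_only' or 'lf_only'")
  if (!object@nClasses %in% 2:4) return("nClasses must be 2, 3 or 4")
  TRUE
})

setMethod("show", "DualFreqNet", function(object) {
  np <- sum(vapply(modelParamModules(object), function(m)
    sum(vapply(m$params, function(p) length(m[[p]]), numeric(1))), numeric(1)))
  cat(sprintf("DualFreqNet (%s): %d classes, %s parameters\n",
              object@mode, object@nClasses, format(np, big.mark = ",")))
})
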