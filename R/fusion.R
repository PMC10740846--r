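# Fusion head: branch feature vectors are concatenated and classified by a
# small fully connected network (hidden width 4, ReLU, dropout, output
# layer), read out through softmax (or a sigmoid for the binary variant).

#' Pool a feature map into a feature vector
#'
#' Default mode applies global average pooling over H x W and returns a
#' length-C vector; `raw = TRUE` flattens the whole map instead (length
#' C*H*W), which is only practical at small sizes.
#'
#' @param f feature map, dim `(C, H, W)` or `(N, C, H, W)`.
#' @param raw flatten without pooling.
#' @return a vector (single map) or matrix (batch).
#' @examples
#' poolAndFlatten(array(2, c(16, 4, 4)))        # rep(2, 16)
#' length(poolAndFlatten(array(0, c(16, 8, 8)), raw = TRUE))
#' @export
poolAndFlatten <- function(f, raw = FALSE) {
  single <- length(dim(f)) == 3L
  if (single) dim(f) <- c(1L, dim(f))
  d <- dim(f)
  y <- if (raw) matrix(f, d[1], prod(d[-1]))
       else matrix(rowMeans(matrix(f, d[1] * d[2], d[3] * d[4])), d[1], d[2])
  if (single) as.numeric(y) else y
}

#' Numerically stable softmax over rows
#' @param x numeric matrix of logits (or a vector).
#' @return matrix (or vector) of probabilities summing to 1 per row.
#' @export
softmaxProbs <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  mx <- apply(x, 1, max)
  e <- exp(x - mx)
  p <- e / rowSums(e)
  if (nrow(p) == 1L && is.null(dim(x))) as.numeric(p) else p
}

#' Cross-entropy loss of logits against an integer class
#'
#' `loss(x, class) = -x[class] + log(sum_i exp(x[i]))`, computed with
#' log-sum-exp stabilisation so large logits cannot overflow.  Always
#' non-negative, and invariant to adding a constant to all logits.
#'
#' @param x logits: a numeric vector, or a matrix (samples x classes).
#' @param class 0-based class label(s).
#' @return the loss (vector input) or mean loss over the batch (matrix).
#' @examples
#' crossEntropyLoss(c(0, 0, 0, 0), 0)   # log(4)
#' crossEntropyLoss(c(1, 0, 0, 0), 0)   # log(exp(1) + 3) - 1
#' @export
crossEntropyLoss <- function(x, class) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  class <- as.integer(class)
  if (any(class < 0L) || any(class >= ncol(x)))
    stop("class label out of range [0, ", ncol(x), ")")
  mx <- apply(x, 1, max)
  lse <- mx + log(rowSums(exp(x - mx)))
  picked <- x[cbind(seq_len(nrow(x)), class + 1L)]
  mean(lse - picked)
}

# loss + gradient for training (gradient of the mean batch loss)
softmaxCrossEntropy <- function(logits, class) {
  n <- nrow(logits)
  p <- softmaxProbs(logits)
  oneHot <- matrix(0, n, ncol(logits))
  oneHot[cbind(seq_len(n), as.integer(class) + 1L)] <- 1
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- mean(lse - logits[cbind(seq_len(n), as.integer(class) + 1L)])
  list(loss = loss, probs = p, dlogits = (p - oneHot) / n)
}

#' Build the fusion classifier head
#'
#' Concatenated branch features go through a fully connected layer with four
#' hidden neurons and ReLU activation, a dropout layer, and a final fully
#' connected layer with `nClasses` outputs.
#'
#' @param inF length of the concatenated feature vector.
#' @param nClasses 2, 3 or 4.
#' @param dropout dropout probability (active only in training).
#' @param hidden hidden width (default 4).
#' @return a module usable with [forwardPass()] on feature matrices.
#' @export
fusionHead <- function(inF, nClasses, dropout = 0.30, hidden = 4L) {
  stopifnot(nClasses %in% 2:4)
  # the output layer starts at zero so the classifier begins at uniform
  # probabilities (loss log K); the hidden biases start slightly positive so
  # none of the four ReLU units is born dead — with so few hidden units a
  # single dead unit costs a quarter of the head's capacity
  hid <- nnLinear(as.integer(inF), as.integer(hidden))
  hid$b <- hid$b + 0.5
  m <- nnSeq(hid, nnReLU(), nnDropout(dropout),
             nnLinear(as.integer(hidden), as.integer(nClasses), zeroInit = TRUE))
  nameModules(m, "head")
  m
}

#' Fuse branch feature vectors and classify
#'
#' Functional form of the fusion head: concatenates the two feature vectors
#' (either may be `NULL` for single-branch ablations) and applies `head`.
#'
#' @param hfVec,lfVec feature vectors (or matrices, samples x features).
#' @param head a module from [fusionHead()].
#' @param training enables dropout.
#' @return a [ClassifierOutput-class] object.
#' @export
fuseAndClassify <- function(hfVec, lfVec, head, training = FALSE) {
  toMat <- function(v) if (is.null(v)) NULL else if (is.null(dim(v))) matrix(v, 1L) else v
  parts <- Filter(Negate(is.null), list(toMat(hfVec), toMat(lfVec)))
  v <- do.call(cbind, parts)
  logits <- moduleForward(head, v, training)
  classifierOutput(logits)
}

classifierOutput <- function(logits, binarySigmoid = FALSE) {
  if (binarySigmoid && ncol(logits) == 2L) {
    # sigmoid on the logit difference: identical ranking to 2-way softmax
    p1 <- 1 / (1 + exp(-(logits[, 2] - logits[, 1])))
    probs <- cbind(1 - p1, p1)
  } else probs <- softmaxProbs(logits)
  new("ClassifierOutput", logits = logits, probs = probs,
      predictedClass = as.integer(apply(probs, 1, which.max) - 1L))
}

# ---- the assembled dual-branch network --------------------------------------

#' Assemble a dual-branch frequency-guided network
#'
#' @param nClasses number of classes (2, 3 or 4).
#' @param mode `"fused"` (both branches), `"hf_only"` or `"lf_only"`.
#' @param hfConfig an [HFConfig-class]; ignored in `"lf_only"` mode.
#' @param lfConfig an [MSDCConfig-class]; ignored in `"hf_only"` mode.
#' @param dropout dropout probability of the fusion head.
#' @param binarySigmoid read a 2-class head out through a sigmoid instead of
#'   softmax (predictions are identical; probabilities are parameterised
#'   differently).
#' @return a [DualFreqNet-class] object.
#' @examples
#' net <- dualFreqNet(4, mode = "lf_only",
#'                    lfConfig = MSDCConfig(channels = 8, nGroups = 1,
#'                                          nBlocksPerGroup = 1))
#' net
#' @export
dualFreqNet <- function(nClasses = 4L, mode = c("fused", "hf_only", "lf_only"),
                        hfConfig = HFConfig(), lfConfig = MSDCConfig(),
                        dropout = 0.30, binarySigmoid = FALSE) {
  mode <- match.arg(mode)
  hf <- if (mode != "lf_only") hfBranch(hfConfig) else NULL
  lf <- if (mode != "hf_only") lfBranch(lfConfig) else NULL
  inF <- sum(c(if (!is.null(hf)) hf$outChannels, if (!is.null(lf)) lf$outChannels))
  head <- fusionHead(inF, nClasses, dropout)
  new("DualFreqNet", mode = mode, nClasses = as.integer(nClasses),
      hfBranch = hf, lfBranch = lf, head = head,
      hfConfig = if (mode != "lf_only") hfConfig else NULL,
      lfConfig = if (mode != "hf_only") lfConfig else NULL,
      binarySigmoid = binarySigmoid)
}

modelParts <- function(net) {
  Filter(Negate(is.null), list(net@hfBranch, net@lfBranch, net@head))
}

modelParamModules <- function(net) {
  unlist(lapply(modelParts(net), collectParamModules), recursive = FALSE)
}

networkForward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  vecs <- list()
  if (!is.null(net@hfBranch))
    vecs$hf <- moduleForward(net@hfBranch, x, training)
  if (!is.null(net@lfBranch))
    vecs$lf <- moduleForward(net@lfBranch, x, training)
  v <- do.call(cbind, vecs)
  logits <- moduleForward(net@head, v, training)
  list(logits = logits, widths = vapply(vecs, ncol, integer(1)))
}

networkBackward <- function(net, dlogits, widths) {
  dv <- moduleBackward(net@head, dlogits)
  off <- 0L
  if (!is.null(net@hfBranch)) {
    moduleBackward(net@hfBranch, dv[, off + seq_len(widths[["hf"]]), drop = FALSE])
    off <- off + widths[["hf"]]
  }
  if (!is.null(net@lfBranch))
    moduleBackward(net@lfBranch, dv[, off + seq_len(widths[["lf"]]), drop = FALSE])
  invisible(NULL)
}

#' Predict class probabilities for a batch of images
#'
#' @param net a [DualFreqNet-class] network.
#' @param x image tensor, dim `(N, 3, H, W)` (or a single `(3, H, W)` image).
#' @param batchSize forward-pass batch size.
#' @return a [ClassifierOutput-class] object.
#' @export
predictNetwork <- function(net, x, batchSize = 16L) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1]
  if (n < 1L) stop("no samples to predict on")
  out <- NULL
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    lo <- networkForward(net, x[idx, , , , drop = FALSE], training = FALSE)$logits
    out <- rbind(out, lo)
  }
  classifierOutput(out, net@binarySigmoid)
}
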