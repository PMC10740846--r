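# Training loop (Adam, mini-batches, learning-curve logging) and the
# evaluation suite: confusion matrix, accuracy / precision / recall / F1
# (per-class and macro), one-vs-rest ROC curves with per-class, micro- and
# macro-average AUC.

#' Train a network by mini-batch gradient descent
#'
#' Minimises the cross-entropy loss with Adam.  The model is updated in
#' place; the return value is the learning-curve table, recorded every
#' `config@logEvery` epochs (training loss/accuracy are epoch averages,
#' validation loss/accuracy come from a full pass in inference mode).  With
#' a fixed seed the run is exactly reproducible.
#'
#' @param model a [DualFreqNet-class] network, or any module whose forward
#'   maps the given `x` to logits (e.g. a [fusionHead()] on feature vectors).
#' @param x training inputs: an `(N, 3, H, W)` image tensor, or an `(N, F)`
#'   feature matrix for plain modules.
#' @param y 0-based integer class labels.
#' @param valX,valY optional validation set.
#' @param config a [TrainConfig-class] object.
#' @return data.frame with columns `epoch`, `trainLoss`, `trainAcc`,
#'   `valLoss`, `valAcc`.
#' @export
trainNetwork <- function(model, x, y, valX = NULL, valY = NULL,
                         config = TrainConfig()) {
  stopifnot(is(config, "TrainConfig"))
  validObject(config)
  n <- if (length(dim(x)) == 4L) dim(x)[1] else nrow(x)
  if (n == 0L) stop("training dataset is empty")
  if (n != length(y)) stop("x and y disagree on the number of samples")
  isNet <- is(model, "DualFreqNet")
  mods <- if (isNet) modelParamModules(model) else collectParamModules(model)
  takeRows <- function(z, idx) {
    if (length(dim(z)) == 4L) z[idx, , , , drop = FALSE] else z[idx, , drop = FALSE]
  }
  set.seed(config@seed)
  step <- 0L
  curves <- NULL
  for (epoch in seq_len(config@epochs)) {
    perm <- sample.int(n)
    epochLoss <- 0
    epochCorrect <- 0L
    for (start in seq(1L, n, by = config@batchSize)) {
      idx <- perm[start:min(start + config@batchSize - 1L, n)]
      xb <- takeRows(x, idx)
      yb <- y[idx]
      if (isNet) {
        fw <- networkForward(model, xb, training = TRUE)
        logits <- fw$logits
      } else {
        logits <- moduleForward(model, xb, training = TRUE)
      }
      sce <- softmaxCrossEntropy(logits, yb)
      if (!is.finite(sce$loss))
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (step ", step + 1L, "); try a lower learning rate")
      zeroGrads(mods)
      if (isNet) networkBackward(model, sce$dlogits, fw$widths)
      else moduleBackward(model, sce$dlogits)
      step <- step + 1L
      adamStep(mods, config@lr, config@beta1, config@beta2, t = step)
      epochLoss <- epochLoss + sce$loss * length(idx)
      epochCorrect <- epochCorrect +
        sum(max.col(sce$probs) - 1L == yb)
    }
    if (epoch %% config@logEvery == 0L) {
      row <- data.frame(epoch = epoch,
                        trainLoss = epochLoss / n,
                        trainAcc = epochCorrect / n,
                        valLoss = NA_real_, valAcc = NA_real_)
      if (!is.null(valX)) {
        ev <- evalLossAcc(model, valX, valY, isNet, config@batchSize)
        row$valLoss <- ev$loss
        row$valAcc <- ev$acc
      }
      curves <- rbind(curves, row)
    }
  }
  curves
}

evalLossAcc <- function(model, x, y, isNet = is(model, "DualFreqNet"),
                        batchSize = 16L) {
  n <- if (length(dim(x)) == 4L) dim(x)[1] else nrow(x)
  loss <- 0
  correct <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    xb <- if (length(dim(x)) == 4L) x[idx, , , , drop = FALSE] else x[idx, , drop = FALSE]
    logits <- if (isNet) networkForward(model, xb, training = FALSE)$logits
              else moduleForward(model, xb, training = FALSE)
    sce <- softmaxCrossEntropy(logits, y[idx])
    loss <- loss + sce$loss * length(idx)
    correct <- correct + sum(max.col(sce$probs) - 1L == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Confusion matrix
#'
#' Entry (i, j) counts samples whose true class is i and predicted class is
#' j (0-based labels, 1-based matrix indices).
#'
#' @param yTrue,yPred equal-length 0-based integer label vectors.
#' @param nClasses number of classes.
#' @return an `nClasses` x `nClasses` integer matrix.
#' @examples
#' confusionMatrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (any(yTrue < 0L | yTrue >= nClasses) || any(yPred < 0L | yPred >= nClasses))
    stop("labels must lie in [0, ", nClasses, ")")
  cm <- matrix(0L, nClasses, nClasses)
  for (i in seq_along(yTrue))
    cm[yTrue[i] + 1L, yPred[i] + 1L] <- cm[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  cm
}

#' F1 score from precision and recall
#' @param precision,recall scalars in [0, 1].
#' @return `2 * P * R / (P + R)`, or 0 when both are 0.
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is trace/total (which for the binary case equals
#' `(TP + TN) / (TP + FP + TN + FN)`).  Per-class precision, recall and F1
#' use one-vs-rest TP/FP/FN/TN; macro averages are unweighted means over
#' classes.  Zero-denominator cells are reported as 0 and flagged.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @return list with `accuracy`, `perClass` (data.frame with tp/fp/fn/tn,
#'   precision, recall, f1, degenerate), and `macro` (named vector with
#'   precision, recall, f1).
#' @export
classificationMetrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  k <- nrow(cm)
  per <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    degP <- (tp + fp) == 0
    degR <- (tp + fn) == 0
    p <- if (degP) 0 else tp / (tp + fp)
    r <- if (degR) 0 else tp / (tp + fn)
    data.frame(class = i - 1L, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = p, recall = r, f1 = f1Score(p, r),
               degenerate = degP || degR)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(diag(cm)) / total,
       perClass = per,
       macro = c(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1)))
}

binaryRocPoints <- function(scores, positive) {
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positive[ord]
  cumTP <- cumsum(p)
  cumFP <- cumsum(!p)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each distinct score
  data.frame(fpr = c(0, cumFP[keep] / nNeg), tpr = c(0, cumTP[keep] / nPos))
}

trapezoidAuc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' One-vs-rest ROC curves and AUCs
#'
#' Per class: a threshold sweep over the unique scores of that class's
#' probability column, TPR = TP/(TP+FN), FPR = FP/(TN+FP), AUC by the
#' trapezoid rule (equal to the probability that a random positive outscores
#' a random negative, ties counted 1/2).  The micro average pools every
#' (sample, class) decision into one binary problem; the macro average
#' interpolates the per-class curves on the union grid of their FPR values
#' and averages them.
#'
#' @param scores matrix of per-class scores (samples x classes), rows
#'   summing to 1 for probability input.
#' @param yTrue 0-based integer labels.
#' @return list with `perClass` (list of data.frames with `fpr`, `tpr`),
#'   `auc` (per-class), `microRoc`, `microAuc`, `macroRoc`, `macroAuc`.
#' @export
rocCurve <- function(scores, yTrue) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  k <- ncol(scores)
  yTrue <- as.integer(yTrue)
  perClass <- vector("list", k)
  auc <- numeric(k)
  for (i in seq_len(k)) {
    pos <- yTrue == (i - 1L)
    if (all(pos) || !any(pos))
      stop("AUC undefined for class ", i - 1L,
           ": it has no positives or no negatives in yTrue")
    perClass[[i]] <- binaryRocPoints(scores[, i], pos)
    auc[i] <- trapezoidAuc(perClass[[i]]$fpr, perClass[[i]]$tpr)
  }
  flatScores <- as.numeric(scores)
  flatTruth <- as.logical(vapply(seq_len(k), function(i) yTrue == (i - 1L),
                                 logical(length(yTrue))))
  microRoc <- binaryRocPoints(flatScores, flatTruth)
  grid <- sort(unique(unlist(lapply(perClass, function(d) d$fpr))))
  interTpr <- vapply(perClass, function(d) {
    stats::approx(d$fpr, d$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  macroRoc <- data.frame(fpr = grid, tpr = rowMeans(interTpr))
  list(perClass = perClass, auc = auc,
       microRoc = microRoc, microAuc = trapezoidAuc(microRoc$fpr, microRoc$tpr),
       macroRoc = macroRoc, macroAuc = trapezoidAuc(macroRoc$fpr, macroRoc$tpr))
}

#' Evaluate a network on a labelled set
#'
#' Runs the network in inference mode and assembles the full evaluation
#' report: confusion matrix, accuracy, per-class and macro
#' precision/recall/F1, and one-vs-rest ROC/AUC (per class, micro, macro).
#'
#' @param net a [DualFreqNet-class] network.
#' @param x `(N, 3, H, W)` image tensor.
#' @param y 0-based integer labels.
#' @param classNames optional class names (defaults to `class0..`).
#' @return an [EvalReport-class] object.
#' @export
evaluateModel <- function(net, x, y, classNames = NULL) {
  out <- predictNetwork(net, x)
  reportFromScores(out@probs, y, classNames)
}

reportFromScores <- function(probs, y, classNames = NULL) {
  k <- ncol(probs)
  if (is.null(classNames)) classNames <- paste0("class", seq_len(k) - 1L)
  pred <- as.integer(apply(probs, 1, which.max) - 1L)
  cm <- confusionMatrix(y, pred, k)
  dimnames(cm) <- list(true = classNames, predicted = classNames)
  met <- classificationMetrics(cm)
  roc <- rocCurve(probs, y)
  names(roc$auc) <- classNames
  new("EvalReport", confusion = cm, accuracy = met$accuracy,
      perClass = met$perClass, macro = met$macro, roc = roc$perClass,
      auc = roc$auc, microRoc = roc$microRoc, macroRoc = roc$macroRoc,
      microAuc = roc$microAuc, macroAuc = roc$macroAuc,
      classNames = classNames)
}

#' Write an evaluation report to disk
#'
#' Serialises the report as `metrics.json` (accuracy, macro metrics,
#' per-class metrics, AUCs), `confusion.csv` and `roc_points.csv` (long
#' format: class, fpr, tpr) under `dir`.
#'
#' @param report an [EvalReport-class] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    accuracy = report@accuracy,
    macro = as.list(report@macro),
    perClass = report@perClass,
    auc = as.list(report@auc),
    microAuc = report@microAuc,
    macroAuc = report@macroAuc)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report@confusion, file.path(dir, "confusion.csv"))
  rocLong <- do.call(rbind, lapply(seq_along(report@roc), function(i) {
    cbind(class = report@classNames[i], report@roc[[i]])
  }))
  utils::write.csv(rocLong, file.path(dir, "roc_points.csv"), row.names = FALSE)
  invisible(dir)
}

# ---- accessor generics ------------------------------------------------------

#' @describeIn EvalReport-class overall accuracy.
#' @param object an `EvalReport`.
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname EvalReport-class
#' @export
setMethod("accuracy", "EvalReport", function(object) object@accuracy)

#' @describeIn EvalReport-class the confusion matrix.
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)

#' @describeIn EvalReport-class named per-class AUCs.
#' @export
setGeneric("aucValues", function(object) standardGeneric("aucValues"))

#' @rdname EvalReport-class
#' @export
setMethod("aucValues", "EvalReport", function(object) object@auc)
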