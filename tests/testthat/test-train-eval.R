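# Evaluation suite: confusion matrices, precision/recall/F1, ROC/AUC with a
# pair-counting oracle and an independent reference implementation; training
# determinism and curve cadence.

test_that("confusion matrix counts by enumeration", {
  cm <- confusionMatrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(cm, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  # perfect predictions: diagonal with row sums equal to class counts
  y <- rep(0:2, times = c(3, 4, 5))
  cmP <- confusionMatrix(y, y, 3)
  expect_equal(diag(cmP), c(3L, 4L, 5L))
  expect_equal(sum(cmP), length(y))
  expect_error(confusionMatrix(c(0, 3), c(0, 0), 2), "lie in")
})

test_that("metrics match hand evaluation of the defining formulas", {
  # binary case TP=3 FP=1 FN=2 TN=4 (class 1 as positive)
  cm <- matrix(c(4L, 2L, 1L, 3L), 2, 2)   # rows true 0/1, cols pred 0/1
  m <- classificationMetrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$perClass$precision[2], 0.75)
  expect_equal(m$perClass$recall[2], 0.6)
  expect_equal(m$perClass$f1[2], 2 / 3)
  expect_error(classificationMetrics(matrix(0, 2, 2)), "empty")
})

test_that("F1 recomputed from printed precision/recall pairs matches reports", {
  expect_equal(round(100 * f1Score(0.739, 1.000), 1), 85.0)
  expect_equal(round(100 * f1Score(0.875, 0.875), 1), 87.5)
  expect_equal(f1Score(0, 0), 0)
})

test_that("macro-F1 of a symmetric confusion matrix equals per-class F1", {
  cm <- matrix(c(8L, 2L, 2L, 8L), 2, 2)
  m <- classificationMetrics(cm)
  expect_equal(m$macro[["f1"]], m$perClass$f1[1])
  expect_equal(m$perClass$f1[1], m$perClass$f1[2])
})

test_that("degenerate one-vs-rest cells are reported as 0 and flagged", {
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, 2)   # class 1 never predicted
  m <- classificationMetrics(cm)
  expect_equal(m$perClass$precision[2], 0)
  expect_true(m$perClass$degenerate[2])
})

test_that("ROC endpoints, monotonicity, and the chance/perfect extremes", {
  y <- rep(c(0L, 1L), each = 10)
  perfect <- cbind(1 - y, y) * 0.8 + 0.1
  r <- rocCurve(perfect, y)
  expect_equal(r$auc, c(1, 1))
  for (d in r$perClass) {
    expect_equal(d$fpr[1], 0); expect_equal(d$tpr[1], 0)
    expect_equal(tail(d$fpr, 1), 1); expect_equal(tail(d$tpr, 1), 1)
    expect_true(all(diff(d$fpr) >= 0) && all(diff(d$tpr) >= 0))
  }
  constant <- matrix(0.5, 20, 2)
  expect_equal(rocCurve(constant, y)$auc, c(0.5, 0.5))
  expect_error(rocCurve(matrix(0.5, 4, 2), rep(0L, 4)), "undefined")
})

test_that("AUC equals exhaustive positive/negative pair counting", {
  set.seed(71)
  for (rep in 1:5) {
    y <- sample(c(0L, 1L), 10, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- round(runif(10), 1)            # coarse scores force ties
    probs <- cbind(1 - s, s)
    auc <- rocCurve(probs, y)$auc[2]
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    expect_equal(auc, mean(pairs))
  }
})

test_that("micro-average accuracy identity and reference cross-check", {
  skip_if_not_installed("pROC")
  set.seed(72)
  n <- 60
  y <- sample(0:2, n, replace = TRUE)
  logits <- matrix(rnorm(3 * n), n, 3) + 1.5 * diag(3)[y + 1, ]
  probs <- softmaxProbs(logits)
  r <- rocCurve(probs, y)
  for (k in 1:3) {
    ref <- pROC::auc(pROC::roc(response = as.integer(y == k - 1),
                               predictor = probs[, k], quiet = TRUE,
                               direction = "<"))
    expect_lt(abs(r$auc[k] - as.numeric(ref)), 1e-9)
  }
  # micro-average over all (sample, class) decisions, against the oracle
  flatT <- as.integer(as.numeric(sapply(1:3, function(k) y == k - 1)))
  refMicro <- pROC::auc(pROC::roc(response = flatT,
                                  predictor = as.numeric(probs),
                                  quiet = TRUE, direction = "<"))
  expect_lt(abs(r$microAuc - as.numeric(refMicro)), 1e-9)
  # single-label micro accuracy equals trace/total accuracy
  pred <- max.col(probs) - 1L
  cm <- confusionMatrix(y, pred, 3)
  expect_equal(classificationMetrics(cm)$accuracy, mean(pred == y))
})

test_that("training is deterministic and logs at the configured cadence", {
  set.seed(73)
  x <- matrix(rnorm(240), 60, 4)
  y <- as.integer(x[, 1] + 0.4 * rnorm(60) > 0)
  mk <- function() {
    set.seed(99)
    fusionHead(4, 2, dropout = 0.3)
  }
  cfg <- TrainConfig(batchSize = 8, epochs = 30, lr = 1e-3, seed = 3407,
                     logEvery = 15, imageSize = 4)
  c1 <- trainNetwork(mk(), x, y, config = cfg)
  c2 <- trainNetwork(mk(), x, y, config = cfg)
  expect_identical(c1, c2)                       # bit-identical curves
  expect_equal(nrow(c1), 30 / 15)                # epochs / logEvery rows
  expect_equal(c1$epoch, c(15, 30))
  expect_error(trainNetwork(mk(), x[0, , drop = FALSE], integer(0), config = cfg),
               "empty")
})

test_that("evaluation report assembles consistently from scores", {
  set.seed(74)
  y <- sample(0:3, 40, replace = TRUE)
  probs <- softmaxProbs(matrix(rnorm(160), 40, 4) + 2 * diag(4)[y + 1, ])
  rep <- df$reportFromScores(probs, y, paste0("c", 0:3))
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(confusion(rep)), 40)
  expect_true(all(aucValues(rep) >= 0 & aucValues(rep) <= 1))
  expect_equal(accuracy(rep),
               classificationMetrics(confusion(rep))$accuracy)
  d <- tempfile()
  writeEvalReport(rep, d)
  expect_true(all(file.exists(file.path(d, c("metrics.json", "confusion.csv",
                                             "roc_points.csv")))))
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$accuracy, accuracy(rep))
})
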