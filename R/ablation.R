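# Desk-scale frequency-specialisation study: trains single-branch and fused
# models on synthetic datasets whose class signal lives in a known frequency
# band, mirroring the architecture's ablation logic at CPU scale.

#' Run the frequency-specialisation ablation study
#'
#' Three synthetic conditions, all 64 x 64, 50 training and 20 test images
#' per class (200 / 80 in total):
#' \describe{
#'   \item{texture}{class signal purely high-frequency (`hfWeight = 1`,
#'     shared blob geometry): the high-frequency branch should outperform
#'     the low-frequency branch.}
#'   \item{shape}{class signal purely low-frequency (`hfWeight = 0`):
#'     the low-frequency branch should outperform.}
#'   \item{mixed}{both signals present: the fused model should be at least
#'     competitive with the better single branch, averaged over
#'     `mixedSeeds` seeds.}
#' }
#' Tiny model variants are used throughout (tiny backbone; low-frequency
#' branch with 8 channels, one group, one block).  Every run uses one
#' uniform protocol — Adam at `lr`, batch 8, the same epoch budget for every
#' model within a condition, dropout disabled — so branch comparisons are
#' not confounded by per-model tuning.  This is a directional experiment,
#' not a reproduction of any full-scale accuracy figure.
#'
#' @param seed master seed; all dataset generation and training derives
#'   from it.
#' @param epochs named list of epoch budgets per condition.
#' @param lr learning rate for all runs.
#' @param mixedSeeds number of seeds the mixed-condition comparison is
#'   averaged over.
#' @param nTrain,nTest images per class for training / test sets.
#' @param size image side length.
#' @param quiet suppress progress output.
#' @return list with per-condition test accuracies: `texture` and `shape`
#'   (named vectors with `hf`, `lf`) and `mixed` (data.frame with one row
#'   per seed and columns `hf`, `lf`, `fused`).
#' @export
runAblationStudy <- function(seed = 1L,
                             epochs = list(texture = 16L, shape = 16L, mixed = 16L),
                             lr = 1e-3, mixedSeeds = 3L,
                             nTrain = 50L, nTest = 20L, size = 64L,
                             quiet = FALSE) {
  seed <- as.integer(seed) %% 100000L
  trainOne <- function(signal, mode, nEpochs, runSeed) {
    specs <- defaultClassSpecs(signal)
    tr <- synthesizeTensors(specs, nTrain, size, masterSeed = runSeed)
    te <- synthesizeTensors(specs, nTest, size, masterSeed = runSeed + 50000L)
    # dropout is disabled at this scale: on a 4-unit hidden layer it removes
    # half the head's capacity at a time and regularly kills units outright
    net <- dualFreqNet(4L, mode = mode, hfConfig = tinyHFConfig(),
                       lfConfig = MSDCConfig(channels = 8L, nGroups = 1L,
                                             nBlocksPerGroup = 1L),
                       dropout = 0)
    tc <- TrainConfig(batchSize = 8L, epochs = nEpochs, lr = lr,
                      seed = runSeed, logEvery = nEpochs, imageSize = size)
    trainNetwork(net, tr$x, tr$y, config = tc)
    acc <- accuracy(evaluateModel(net, te$x, te$y))
    if (!quiet)
      message(sprintf("  %-7s %-8s seed %-6d: test accuracy %.3f",
                      signal, mode, runSeed, acc))
    acc
  }
  out <- list()
  for (signal in c("texture", "shape")) {
    out[[signal]] <- c(
      hf = trainOne(signal, "hf_only", epochs[[signal]], seed),
      lf = trainOne(signal, "lf_only", epochs[[signal]], seed))
  }
  rows <- lapply(seq_len(mixedSeeds), function(k) {
    s <- seed + k - 1L
    data.frame(seed = s,
               hf = trainOne("mixed", "hf_only", epochs$mixed, s),
               lf = trainOne("mixed", "lf_only", epochs$mixed, s),
               fused = trainOne("mixed", "fused", epochs$mixed, s))
  })
  out$mixed <- do.call(rbind, rows)
  out
}
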