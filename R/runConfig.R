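#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the reference analysis design: 10x repeated 5-fold outer CV with 5 inner
#' folds, 5% outlier trimming by a 500-tree isolation forest, the > 95%
#' zero-prevalence filter, the > 1% mean-abundance genus filter, 10,000
#' permutations for the min-p correction, highlight threshold |r| > 0.3 at
#' alpha 0.05, and 7 genus / 9 metabolite clusters.
#'
#' @param table which table the classifier runs on: `"abundance"` or
#'   `"peaks"`.
#' @param folds,repeats,innerFolds cross-validation structure.
#' @param outlierFrac training-fold fraction trimmed as outliers.
#' @param isolationTrees isolation-forest size.
#' @param zeroPrevalenceCutoff remove features zero in more than this
#'   fraction of samples.
#' @param overallAbundanceCutoff keep genera with mean relative abundance
#'   strictly above this.
#' @param nPermutations permutations for the min-p correction.
#' @param alpha significance level.
#' @param rHighlight |partial r| threshold of the highlight mask.
#' @param kGenusClusters,kMetaboliteClusters Ward tree cut sizes.
#' @param rarefactionPoints depths per rarefaction curve.
#' @param zoo candidate learners, from [modelZoo()].
#' @param hillClimbBudget consecutive non-improving hill-climb iterations
#'   before stopping.
#' @param hillClimbMaxIters hard cap on total hill-climb iterations per
#'   outer cell (default `10 * hillClimbBudget`).
#' @param relearnEvery accepted moves between learner re-selections.
#' @param seed integer master seed.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(table = "abundance",
                      folds = 5L, repeats = 10L, innerFolds = 5L,
                      outlierFrac = 0.05, isolationTrees = 500L,
                      zeroPrevalenceCutoff = 0.95,
                      overallAbundanceCutoff = 0.01,
                      nPermutations = 10000L, alpha = 0.05,
                      rHighlight = 0.3,
                      kGenusClusters = 7L, kMetaboliteClusters = 9L,
                      rarefactionPoints = 10L,
                      zoo = modelZoo(500L),
                      hillClimbBudget = 200L,
                      hillClimbMaxIters = 10L * hillClimbBudget,
                      relearnEvery = 25L,
                      seed = 1L) {
  cfg <- list(table = table, folds = as.integer(folds),
              repeats = as.integer(repeats),
              innerFolds = as.integer(innerFolds),
              outlierFrac = outlierFrac,
              isolationTrees = as.integer(isolationTrees),
              zeroPrevalenceCutoff = zeroPrevalenceCutoff,
              overallAbundanceCutoff = overallAbundanceCutoff,
              nPermutations = as.integer(nPermutations), alpha = alpha,
              rHighlight = rHighlight,
              kGenusClusters = as.integer(kGenusClusters),
              kMetaboliteClusters = as.integer(kMetaboliteClusters),
              rarefactionPoints = as.integer(rarefactionPoints),
              zoo = zoo,
              hillClimbBudget = as.integer(hillClimbBudget),
              hillClimbMaxIters = as.integer(hillClimbMaxIters),
              relearnEvery = as.integer(relearnEvery),
              seed = as.integer(seed))
  stopifnot(cfg$folds >= 2L, cfg$innerFolds >= 2L,
            cfg$outlierFrac >= 0, cfg$outlierFrac < 0.5,
            cfg$nPermutations >= 1L,
            cfg$zeroPrevalenceCutoff > 0, cfg$zeroPrevalenceCutoff < 1,
            cfg$overallAbundanceCutoff > 0, cfg$overallAbundanceCutoff < 1,
            cfg$hillClimbBudget >= 1L)
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) {
    v <- flat[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
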