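## Shared fixtures: small cohorts built in code, sized for fast unit tests.

smallConfig <- function(seed = 1L, ...) {
  cohortConfig(groupSizes = c(HC = 12L, SLE = 12L, SjS = 10L),
               nGenera = 40L, nPeaks = 60L,
               nDiscriminativeGenera = 4L, nDiscriminativePeaks = 5L,
               nCorrBlocks = 1L, seed = seed, ...)
}

smallCohort <- function(seed = 1L, ...) generateCohort(smallConfig(seed, ...))

## quick run configuration for classifier tests
quickRunConfig <- function(seed = 1L, ...) {
  runConfig(repeats = 1L, zoo = modelZoo(30L), hillClimbBudget = 5L,
            isolationTrees = 30L, seed = seed, ...)
}

## two-class separable toy: one informative feature, the rest noise
separableData <- function(n = 40L, p = 6L, seed = 1L) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  x[, 1L] <- ifelse(y == "a", -3, 3) + rnorm(n, 0, 0.3)
  list(x = x, y = y)
}
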