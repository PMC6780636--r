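#' Genus-level overall-abundance filter
#'
#' Keeps genera whose mean relative abundance across samples exceeds the
#' cutoff (strictly), preserving column order.
#'
#' @param abundance samples x genera relative-abundance matrix.
#' @param cutoff mean-proportion threshold, default 0.01 (i.e. 1%).
#' @return The column-reduced matrix.
#' @export
filterGenusAbundance <- function(abundance, cutoff = 0.01) {
  keep <- colMeans(abundance) > cutoff
  if (!any(keep))
    stop("overall-abundance filter removed every genus (cutoff = ",
         cutoff, ")")
  abundance[, keep, drop = FALSE]
}

#' Zero-prevalence filter
#'
#' Removes features that are zero in strictly more than `cutoff` of the
#' samples (default: > 95% zeros).
#'
#' @param table samples x features matrix.
#' @param cutoff zero-fraction threshold in (0, 1).
#' @return The column-reduced matrix (possibly unchanged).
#' @export
filterZeroPrevalence <- function(table, cutoff = 0.95) {
  zf <- colMeans(table == 0)
  table[, zf <= cutoff, drop = FALSE]
}

#' MSTUS normalization of metabolite peak areas
#'
#' Divides each sample's peak areas by its total useful signal: the summed
#' intensity over the peaks detected (nonzero) in every sample. When no
#' peak is complete across all samples, the divisor falls back to each
#' sample's total signal over all peaks, with a warning.
#'
#' @param peaks samples x peaks non-negative matrix.
#' @return The row-normalized matrix.
#' @export
mstusNormalize <- function(peaks) {
  useful <- colSums(peaks == 0) == 0L
  if (!any(useful)) {
    warning("no peak detected in every sample; MSTUS divisor falls back ",
            "to total signal over all peaks")
    useful <- rep(TRUE, ncol(peaks))
  }
  divisor <- rowSums(peaks[, useful, drop = FALSE])
  bad <- divisor <= 0
  if (any(bad))
    stop("zero total useful signal for sample(s): ",
         paste(rownames(peaks)[bad], collapse = ", "))
  peaks / divisor
}

#' Isolation-forest anomaly scores
#'
#' Standard isolation forest: trees grown on random subsamples with uniform
#' random splits; the anomaly score of a point is `2^(-E[pathlength]/c(psi))`
#' (near 1 for points isolated quickly, near 0.5 and below for inliers).
#'
#' @param x numeric matrix (samples x features).
#' @param nTrees number of isolation trees.
#' @param subsampleSize per-tree subsample size (capped at `nrow(x)`).
#' @param seed integer seed.
#' @return Numeric vector of anomaly scores, one per row of `x`.
#' @export
isolationScore <- function(x, nTrees = 500L, subsampleSize = 256L, seed = 1L) {
  set.seed(as.integer(seed))
  .iforestScore(as.matrix(x), as.integer(nTrees), as.integer(subsampleSize))
}

#' Fit per-fold preprocessing: standardization + outlier trimming
#'
#' On a training fold: (1) standardize every feature to zero mean / unit
#' variance; (2) fit an isolation forest on the standardized data and remove
#' exactly `floor(outlierFrac * n)` samples with the highest anomaly scores;
#' (3) re-estimate location and scale on the retained samples. Constant
#' features get scale 1 (with a warning): they carry no information but are
#' not an error.
#'
#' @param train samples x features numeric matrix (training fold only).
#' @param outlierFrac fraction of training samples to trim, in \[0, 0.5).
#' @param nTrees isolation-forest size.
#' @param seed integer seed for the forest.
#' @return A `FoldPreprocess` list: `center`, `scale` (per retained
#'   statistics), `removed` (ids/indices of trimmed samples), `scores`,
#'   `features`.
#' @export
fitFoldPreprocess <- function(train, outlierFrac = 0.05, nTrees = 500L,
                              seed = 1L) {
  stopifnot(outlierFrac >= 0, outlierFrac < 0.5)
  n <- nrow(train)
  std <- function(m) {
    ctr <- colMeans(m)
    sc <- apply(m, 2L, stats::sd)
    const <- !is.finite(sc) | sc == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s); scale set to 1")
      sc[const] <- 1
    }
    list(center = ctr, scale = sc)
  }
  s0 <- std(train)
  nRemove <- floor(outlierFrac * n)
  removed <- integer(0)
  scores <- rep(NA_real_, n)
  if (nRemove > 0L) {
    z <- sweep(sweep(train, 2L, s0$center), 2L, s0$scale, "/")
    scores <- isolationScore(z, nTrees = nTrees, seed = seed)
    removed <- order(scores, decreasing = TRUE)[seq_len(nRemove)]
  }
  kept <- setdiff(seq_len(n), removed)
  s1 <- suppressWarnings(std(train[kept, , drop = FALSE]))
  structure(list(center = s1$center, scale = s1$scale,
                 removed = removed,
                 removedIds = rownames(train)[removed],
                 keptIds = rownames(train)[kept],
                 scores = scores,
                 features = colnames(train)),
            class = "FoldPreprocess")
}

#' Apply a fitted fold-preprocessing model
#'
#' Applies the training-fold location/scale to new samples. Never removes
#' test samples.
#'
#' @param model a `FoldPreprocess` from [fitFoldPreprocess()].
#' @param table samples x features matrix with the model's features.
#' @return The standardized matrix.
#' @export
applyFoldPreprocess <- function(model, table) {
  if (!identical(colnames(table), model$features))
    stop("feature mismatch between preprocessing model and table")
  sweep(sweep(table, 2L, model$center), 2L, model$scale, "/")
}
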