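#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + s1 (s1 - 1) / (2 (s2 + 1))` with `s1` singletons and `s2`
#' doubletons; the bias-corrected variant stays finite when no doubletons
#' are observed.
#'
#' @param counts non-negative integer counts for one sample.
#' @return The richness estimate (numeric scalar).
#' @examples
#' chao1(c(5, 3, 1, 1))  # 5
#' @export
chao1 <- function(counts) {
  .checkCounts(counts)
  est <- vegan::estimateR(matrix(as.integer(round(counts)), nrow = 1L))
  unname(est["S.chao1", 1L])
}

#' Shannon entropy of a count vector
#'
#' `H = -sum(p_i log p_i)` over nonzero proportions; natural logarithm by
#' default.
#'
#' @param counts non-negative counts with positive total.
#' @param base logarithm base (default `exp(1)`).
#' @return Entropy (numeric scalar).
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  .checkCounts(counts)
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

.checkCounts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("all-zero sample: diversity undefined")
  invisible(TRUE)
}

#' Monte-Carlo rarefaction curve for one sample
#'
#' At each of `nPoints` evenly spaced depths up to `maxDepth`, subsamples
#' the counts without replacement `nDraws` times and averages the requested
#' index. The mean rarefied richness agrees with the closed-form
#' hypergeometric expectation (see `vegan::rarefy`) up to Monte-Carlo error.
#'
#' @param counts non-negative integer counts for one sample.
#' @param nPoints number of depths (default 10).
#' @param maxDepth deepest subsample; capped at the sample total with a
#'   warning when larger.
#' @param index one of `"richness"`, `"chao1"`, `"shannon"`.
#' @param nDraws Monte-Carlo draws per depth.
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean`, `sd`.
#' @export
rarefactionCurve <- function(counts, nPoints = 10L, maxDepth = sum(counts),
                             index = c("richness", "chao1", "shannon"),
                             nDraws = 10L, seed = 1L) {
  index <- match.arg(index)
  .checkCounts(counts)
  counts <- as.integer(round(counts))
  total <- sum(counts)
  if (maxDepth > total) {
    warning("maxDepth ", maxDepth, " exceeds sample total ", total,
            "; capped")
    maxDepth <- total
  }
  if (maxDepth < 1) stop("depth must be >= 1")
  depths <- unique(pmax(1L, round(seq(maxDepth / nPoints, maxDepth,
                                      length.out = nPoints))))
  idxFun <- switch(index,
    richness = function(x) sum(x > 0),
    chao1 = chao1,
    shannon = shannon)
  pool <- rep.int(seq_along(counts), counts)
  set.seed(as.integer(seed))
  out <- lapply(depths, function(d) {
    vals <- vapply(seq_len(nDraws), function(i) {
      sub <- tabulate(sample(pool, d), nbins = length(counts))
      idxFun(sub)
    }, numeric(1))
    c(mean = mean(vals), sd = stats::sd(vals))
  })
  out <- do.call(rbind, out)
  data.frame(depth = depths, mean = out[, "mean"], sd = out[, "sd"])
}

#' Alpha-diversity summary of a count table
#'
#' Chao1 and Shannon indices for every sample of a samples x taxa count
#' matrix.
#'
#' @param counts samples x taxa integer matrix.
#' @return data.frame with columns `sample`, `chao1`, `shannon`.
#' @export
alphaDiversity <- function(counts) {
  data.frame(
    sample = rownames(counts),
    chao1 = apply(counts, 1L, chao1),
    shannon = apply(counts, 1L, shannon),
    row.names = NULL
  )
}
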