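#' Kruskal-Wallis screening with FDR correction
#'
#' Tie-corrected Kruskal-Wallis test per feature across the groups,
#' Benjamini-Hochberg adjustment across features, and a significance flag
#' at `alpha`. Features constant across all samples get p = 1 with a note
#' in the `note` column.
#'
#' @param table samples x features numeric matrix.
#' @param labels factor of group labels (>= 2 groups, >= 2 samples each).
#' @param alpha significance level after FDR correction.
#' @return data.frame: `feature`, `H`, `p`, `padj`, `significant`, `note`.
#' @export
kruskalFDR <- function(table, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  res <- lapply(colnames(table), function(f) {
    v <- table[, f]
    if (max(v) == min(v))
      return(data.frame(feature = f, H = 0, p = 1,
                        note = "constant feature"))
    kw <- stats::kruskal.test(v, labels)
    data.frame(feature = f, H = unname(kw$statistic), p = kw$p.value,
               note = "")
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj < alpha
  out[, c("feature", "H", "p", "padj", "significant", "note")]
}

#' Dunn's pairwise post-hoc test
#'
#' Dunn's z statistics from pooled ranks with tie correction, with
#' two-sided p-values per group pair. Intended as follow-up for features
#' flagged by [kruskalFDR()]; p-values are unadjusted across pairs by
#' default.
#'
#' @param values numeric vector (one feature).
#' @param labels factor of group labels.
#' @param padjMethod adjustment across pairs (`"none"` default; any
#'   [stats::p.adjust()] method).
#' @return data.frame: `groupA`, `groupB`, `z`, `p`, `padj`. Pairs with a
#'   group of fewer than 2 samples are skipped with a warning.
#' @export
dunnPairwise <- function(values, labels, padjMethod = "none") {
  labels <- droplevels(factor(labels))
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRank <- tapply(r, labels, mean)
  n <- table(labels)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    if (n[a] < 2L || n[b] < 2L) {
      warning("pair ", a, "-", b, " skipped: group with < 2 samples")
      return(NULL)
    }
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[a] + 1 / n[b]))
    z <- if (se == 0) 0 else (meanRank[a] - meanRank[b]) / se
    data.frame(groupA = a, groupB = b, z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no evaluable group pair")
  out$padj <- stats::p.adjust(out$p, method = padjMethod)
  rownames(out) <- NULL
  out
}

#' Screen selected features: KW + FDR, then Dunn where significant
#'
#' The univariate follow-up applied to classifier-selected features: every
#' feature is tested by Kruskal-Wallis; features significant after BH
#' correction at `alpha` get Dunn pairwise comparisons.
#'
#' @inheritParams kruskalFDR
#' @param features optional character vector restricting the screen.
#' @return list with `kruskal` (the [kruskalFDR()] table) and `dunn`
#'   (named list of [dunnPairwise()] tables for the flagged features).
#' @export
posthocScreen <- function(table, labels, features = colnames(table),
                          alpha = 0.05) {
  tab <- table[, features, drop = FALSE]
  kw <- kruskalFDR(tab, labels, alpha = alpha)
  flagged <- kw$feature[kw$significant]
  dunn <- lapply(flagged, function(f) dunnPairwise(tab[, f], labels))
  names(dunn) <- flagged
  list(kruskal = kw, dunn = dunn)
}
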