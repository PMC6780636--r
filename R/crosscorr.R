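#' Partial Pearson correlation via residuals
#'
#' Regresses `y` and `z` each on `[1, X]` by ordinary least squares and
#' returns the Pearson correlation of the two residual vectors. With an
#' empty `X` this reduces to the plain Pearson correlation.
#'
#' @param y,z numeric vectors of equal length (dependent / independent
#'   variable).
#' @param X numeric matrix of covariates (may have zero columns or be
#'   NULL).
#' @return Partial correlation coefficient; `NaN` (with a warning) when a
#'   residual vector is numerically zero, i.e. the variable is collinear
#'   with the covariates.
#' @export
partialCorr <- function(y, z, X = NULL) {
  n <- length(y)
  stopifnot(length(z) == n)
  if (is.null(X) || NCOL(X) == 0L) {
    ry <- y - mean(y); rz <- z - mean(z)
  } else {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
    if (n <= ncol(X) + 2L)
      stop("need n > ncol(X) + 2 observations")
    qrX <- qr(cbind(1, X))
    ry <- qr.resid(qrX, y)
    rz <- qr.resid(qrX, z)
  }
  tol <- 1e-12 * n
  if (sum(ry^2) <= tol || sum(rz^2) <= tol) {
    warning("residual vector numerically zero: partial correlation undefined")
    return(NaN)
  }
  sum(ry * rz) / sqrt(sum(ry^2) * sum(rz^2))
}

## Residualize every column of M on [1, X]; returns the residual matrix.
.residualize <- function(M, X) {
  if (is.null(X) || NCOL(X) == 0L) return(scale(M, scale = FALSE))
  qr.resid(qr(cbind(1, as.matrix(X))), M)
}

## Cross-correlation of two residual matrices, column vs column.
.resCor <- function(RG, RM) {
  sg <- sqrt(colSums(RG^2)); sm <- sqrt(colSums(RM^2))
  r <- crossprod(RG, RM) / outer(sg, sm)
  r[!is.finite(r)] <- NaN
  r
}

#' Genus x metabolite partial cross-correlation matrix
#'
#' Entry (g, m) is the partial Pearson correlation of metabolite m
#' (dependent) with genus g (independent), each residualized on the
#' confounders. Samples with missing confounders are dropped with a
#' message.
#'
#' @param G samples x genera matrix.
#' @param M samples x metabolites matrix (same samples, same order).
#' @param X samples x covariates confounder matrix (or NULL).
#' @return A [CrossCorrResult-class] without p-values (see [pminAdjust()]).
#' @export
crossCorrMatrix <- function(G, M, X = NULL) {
  stopifnot(nrow(G) == nrow(M))
  keep <- if (is.null(X)) rep(TRUE, nrow(G)) else stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) with missing confounders dropped")
    G <- G[keep, , drop = FALSE]; M <- M[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  RG <- .residualize(G, X)
  RM <- .residualize(M, X)
  r <- .resCor(RG, RM)
  dimnames(r) <- list(colnames(G), colnames(M))
  new("CrossCorrResult", r = r, pRaw = NULL, pAdj = NULL, mask = NULL,
      confounders = colnames(X) %||% character(),
      B = 0L, alpha = NA_real_, rHighlight = NA_real_, seed = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Westfall-Young step-down min-p permutation correction
#'
#' Builds the permutation null by permuting the rows of the metabolite
#' block as a whole against fixed genera and confounders (preserving the
#' correlation structure within the metabolome, which the min-p method
#' requires), recomputing the full partial-correlation matrix for each of
#' the `B` permutations. Raw p-values use the `(1 + count) / (B + 1)`
#' convention; adjusted p-values follow the step-down min-p algorithm and
#' are monotone in the raw-p ordering and never smaller than the raw p.
#'
#' @inheritParams crossCorrMatrix
#' @param B number of permutations.
#' @param seed integer seed.
#' @param alpha,rHighlight thresholds for the highlight mask
#'   (`pAdj < alpha` and `|r| > rHighlight`).
#' @return A [CrossCorrResult-class] with `r`, `pRaw`, `pAdj` and `mask`.
#' @export
pminAdjust <- function(G, M, X = NULL, B = 10000L, seed = 1L,
                       alpha = 0.05, rHighlight = 0.3) {
  stopifnot(B >= 1L)
  if (1 / (B + 1) > alpha)
    warning("B = ", B, " is too small for alpha = ", alpha,
            ": no entry can reach significance")
  keep <- if (is.null(X)) rep(TRUE, nrow(G)) else stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) with missing confounders dropped")
    G <- G[keep, , drop = FALSE]; M <- M[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(G)
  qrX <- if (is.null(X) || NCOL(X) == 0L) NULL else qr(cbind(1, as.matrix(X)))
  resid <- function(mat) if (is.null(qrX)) scale(mat, scale = FALSE)
                         else qr.resid(qrX, mat)
  RG <- resid(G)
  rObs <- .resCor(RG, resid(M))
  nG <- ncol(G); nM <- ncol(M); mEnt <- nG * nM
  aObs <- abs(as.vector(rObs))
  set.seed(as.integer(seed))
  ABS <- matrix(NA_real_, B, mEnt)
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    ABS[b, ] <- abs(as.vector(.resCor(RG, resid(M[idx, , drop = FALSE]))))
  }
  ## entries with undefined correlation (constant columns) are excluded
  ## from the procedure and reported as NA
  valid <- which(is.finite(aObs) & colSums(!is.finite(ABS)) == 0L)
  pRaw <- pAdj <- rep(NA_real_, mEnt)
  if (length(valid)) {
    AV <- ABS[, valid, drop = FALSE]
    aV <- aObs[valid]
    nV <- length(valid)
    ## raw permutation p per entry
    exceed <- colSums(AV >= rep(aV, each = B) - 1e-14)
    pRaw[valid] <- (1 + exceed) / (B + 1)
    ## per-permutation entry p-values from the same null, on the same
    ## (1 + count)/(B + 1) scale as pRaw (self excluded from the count so
    ## the attainable floor matches pRaw's floor of 1/(B+1))
    P <- apply(AV, 2L, function(col)
      (1 + B - rank(col, ties.method = "min")) / (B + 1))
    P <- matrix(P, nrow = B)
    ## step-down: successive minima over entries ordered by raw p
    ord <- order(pRaw[valid])
    Q <- P[, ord, drop = FALSE]
    if (nV > 1L)
      for (j in (nV - 1L):1L) Q[, j] <- pmin(Q[, j], Q[, j + 1L])
    pAdjOrd <- vapply(seq_len(nV), function(j)
      (1 + sum(Q[, j] <= pRaw[valid][ord[j]] + 1e-14)) / (B + 1), numeric(1))
    pAdjOrd <- cummax(pAdjOrd)
    pAdjV <- numeric(nV)
    pAdjV[ord] <- pAdjOrd
    pAdj[valid] <- pAdjV
  }
  pRawM <- matrix(pRaw, nG, nM, dimnames = dimnames(rObs))
  pAdjM <- matrix(pAdj, nG, nM, dimnames = dimnames(rObs))
  mask <- pAdjM < alpha & abs(rObs) > rHighlight
  mask[!is.finite(rObs) | is.na(pAdjM)] <- FALSE
  new("CrossCorrResult", r = rObs, pRaw = pRawM, pAdj = pAdjM, mask = mask,
      confounders = colnames(X) %||% character(), B = as.integer(B),
      alpha = alpha, rHighlight = rHighlight, seed = as.integer(seed))
}

#' Ward bi-clustering of the cross-correlation matrix
#'
#' Genera are clustered on their rows of the partial-r matrix, metabolites
#' on the columns (Euclidean distance on r-profiles, Ward linkage,
#' `ward.D2`), and each tree is cut at the requested number of clusters —
#' the explicit, reproducible counterpart of cutting the dendrogram by
#' inspection.
#'
#' @param r numeric genus x metabolite matrix of partial correlations.
#' @param kG,kM number of genus / metabolite clusters (defaults 7 and 9).
#' @return A [ClusterModel-class] (assignments and dendrograms only).
#' @export
clusterBidirectional <- function(r, kG = 7L, kM = 9L) {
  if (any(!is.finite(r))) stop("r matrix must be finite")
  if (kG < 1L || kG > nrow(r)) stop("kG out of range")
  if (kM < 1L || kM > ncol(r)) stop("kM out of range")
  tG <- stats::hclust(stats::dist(r), method = "ward.D2")
  tM <- stats::hclust(stats::dist(t(r)), method = "ward.D2")
  new("ClusterModel",
      genusClusters = stats::cutree(tG, k = kG),
      metaboliteClusters = stats::cutree(tM, k = kM),
      genusTree = tG, metaboliteTree = tM,
      genusCentroids = NULL, metaboliteCentroids = NULL,
      simplified = NULL)
}

## per-sample cluster centroids: mean raw value over the cluster's features
.centroids <- function(table, assignment, prefix) {
  ks <- sort(unique(assignment))
  cent <- vapply(ks, function(k) {
    feats <- names(assignment)[assignment == k]
    if (!length(feats)) stop("empty cluster ", k)
    rowMeans(table[, feats, drop = FALSE])
  }, numeric(nrow(table)))
  colnames(cent) <- paste0(prefix, ks)
  rownames(cent) <- rownames(table)
  cent
}

#' Centroid-aggregated simplified cross-correlation matrix
#'
#' Computes per-sample cluster centroids — the mean raw relative abundance
#' (genus clusters) and mean raw peak area (metabolite clusters) — and runs
#' the full partial-correlation + min-p pipeline on the centroid tables.
#' With all-singleton clusters this reproduces the unaggregated matrix
#' entrywise.
#'
#' @param data a [MultiOmicCohort-class].
#' @param model a [ClusterModel-class] whose assignments cover features of
#'   the cohort tables.
#' @param X confounder matrix (default [confounderMatrix()] of the cohort).
#' @param B permutations for [pminAdjust()].
#' @param seed integer seed.
#' @param alpha,rHighlight highlight-mask thresholds.
#' @return The input [ClusterModel-class] with centroid tables and the
#'   `simplified` [CrossCorrResult-class] filled in.
#' @export
centroidSimplifiedMatrix <- function(data, model, X = confounderMatrix(data),
                                     B = 10000L, seed = 1L, alpha = 0.05,
                                     rHighlight = 0.3) {
  stopifnot(is(data, "MultiOmicCohort"), is(model, "ClusterModel"))
  gc <- .centroids(abundances(data), model@genusClusters, "G")
  mc <- .centroids(peakAreas(data), model@metaboliteClusters, "M")
  simp <- pminAdjust(gc, mc, X, B = B, seed = seed, alpha = alpha,
                     rHighlight = rHighlight)
  initialize(model, genusCentroids = gc, metaboliteCentroids = mc,
             simplified = simp)
}

#' Full cross-correlation analysis of a cohort
#'
#' Convenience wrapper running, in order: the genus filters, the
#' confounder-adjusted partial cross-correlation with min-p permutation
#' correction, Ward bi-clustering, and the centroid-aggregated simplified
#' matrix.
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param config a [runConfig()] list (uses `nPermutations`, `alpha`,
#'   `rHighlight`, `kGenusClusters`, `kMetaboliteClusters`, `seed`,
#'   `overallAbundanceCutoff`, `zeroPrevalenceCutoff`).
#' @return list with `result` (full [CrossCorrResult-class]) and `clusters`
#'   (the [ClusterModel-class] including the simplified matrix).
#' @export
crossCorrelate <- function(cohort, config = runConfig()) {
  G <- filterZeroPrevalence(
    filterGenusAbundance(abundances(cohort), config$overallAbundanceCutoff),
    config$zeroPrevalenceCutoff)
  M <- mstusNormalize(peakAreas(cohort))
  X <- confounderMatrix(cohort)
  res <- pminAdjust(G, M, X, B = config$nPermutations, seed = config$seed,
                    alpha = config$alpha, rHighlight = config$rHighlight)
  cl <- clusterBidirectional(partialR(res), kG = config$kGenusClusters,
                             kM = config$kMetaboliteClusters)
  cl <- centroidSimplifiedMatrix(cohort, cl, X, B = config$nPermutations,
                                 seed = config$seed, alpha = config$alpha,
                                 rHighlight = config$rHighlight)
  list(result = res, clusters = cl)
}
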