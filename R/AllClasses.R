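#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Configuration of a synthetic multi-omic cohort
#'
#' Holds every knob of the synthetic cohort generator: group sizes, table
#' dimensions, the number and strength of planted discriminative features,
#' the latent genus-metabolite correlation blocks, confounder coefficients
#' and zero inflation. Construct with [cohortConfig()].
#'
#' @slot groupSizes named integer vector, samples per clinical group.
#' @slot nGenera,nPeaks number of genera / metabolite peaks.
#' @slot nDiscriminativeGenera,nDiscriminativePeaks number of features that
#'   receive group-specific log-scale shifts.
#' @slot effectSize standardized log-scale mean-shift magnitude (residual
#'   log SD is 1, so this is in units of within-group SD).
#' @slot nCorrBlocks number of latent genus-metabolite correlation blocks.
#' @slot blockCorr target raw-scale Pearson correlation within a block.
#' @slot confounderStrength SD of per-feature age/drug coefficients.
#' @slot zeroInflation mean structural-absence probability of a genus.
#' @slot seed integer RNG seed.
#'
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    groupSizes = "integer",
    nGenera = "integer",
    nPeaks = "integer",
    nDiscriminativeGenera = "integer",
    nDiscriminativePeaks = "integer",
    effectSize = "numeric",
    nCorrBlocks = "integer",
    blockCorr = "numeric",
    confounderStrength = "numeric",
    zeroInflation = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@groupSizes) == 0L || is.null(names(object@groupSizes)))
    msg <- c(msg, "groupSizes must be a non-empty named vector")
  if (any(object@groupSizes < 0L)) msg <- c(msg, "group sizes must be >= 0")
  if (any(c(object@nGenera, object@nPeaks, object@nDiscriminativeGenera,
            object@nDiscriminativePeaks, object@nCorrBlocks) < 0L))
    msg <- c(msg, "all counts must be >= 0")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (abs(object@blockCorr) >= 1) msg <- c(msg, "|blockCorr| must be < 1")
  if (object@zeroInflation < 0 || object@zeroInflation >= 1)
    msg <- c(msg, "zeroInflation must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Paired microbiome-metabolome cohort
#'
#' The central data container: a genus-level relative-abundance matrix and a
#' metabolite peak-area matrix over the same samples (rows), plus per-sample
#' metadata (clinical group, age, and three binary treatment flags used as
#' confounders). Generated cohorts additionally carry a truth ledger
#' recording which features and blocks received planted signal.
#'
#' @slot abundance numeric matrix, samples x genera; rows sum to 1.
#' @slot peaks numeric matrix, samples x peaks; non-negative.
#' @slot sampleData data.frame with columns `group` (factor), `age`,
#'   `hcq`, `prednisone_gt5`, `immunosuppressant` (0/1 flags).
#' @slot truth list describing planted effects (empty for read-in data).
#'
#' @seealso [generateCohort()], [readCohort()], [abundances()],
#'   [peakAreas()], [sampleData()], [plantedTruth()]
#' @exportClass MultiOmicCohort
setClass("MultiOmicCohort",
  representation(
    abundance = "matrix",
    peaks = "matrix",
    sampleData = "data.frame",
    truth = "list"
  )
)

setValidity("MultiOmicCohort", function(object) {
  msg <- character()
  ids <- rownames(object@abundance)
  if (is.null(ids)) return("abundance must have sample ids as rownames")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated sample ids")
  if (!identical(ids, rownames(object@peaks)) ||
      !identical(ids, rownames(object@sampleData)))
    msg <- c(msg, "sample ids must be identical, in order, across tables")
  if (any(object@abundance < 0) || any(object@peaks < 0))
    msg <- c(msg, "negative entries are not allowed")
  if (any(abs(rowSums(object@abundance) - 1) > 1e-9))
    msg <- c(msg, "abundance rows must sum to 1 within 1e-9")
  need <- c("group", "age", "hcq", "prednisone_gt5", "immunosuppressant")
  if (!all(need %in% colnames(object@sampleData)))
    msg <- c(msg, paste("sampleData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Repeated nested cross-validation fold plan
#'
#' Stratified sample-id assignments for a repeated outer cross-validation,
#' each outer training set further split into inner folds for model and
#' feature selection. Within each repeat the outer test folds partition the
#' cohort; within each outer cell the inner folds partition the outer
#' training set.
#'
#' @slot plan nested list: `plan[[repeat]][[outerFold]]` is a list with
#'   `train`, `test` (character sample ids) and `inner`, itself a list of
#'   `list(train, test)` cells indexing into the outer training set.
#' @slot repeats,outerFolds,innerFolds plan dimensions.
#' @slot seed integer seed the plan was drawn with.
#'
#' @seealso [buildFoldPlan()]
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(
    plan = "list",
    repeats = "integer",
    outerFolds = "integer",
    innerFolds = "integer",
    seed = "integer"
  )
)

#' One-vs-one classification metrics
#'
#' Balanced accuracy, F1 and AUROC for every unordered class pair, with the
#' weighted mean over pairs (weights proportional to the number of samples
#' in each pairwise restriction) and, when computed across repeated
#' cross-validation, the dispersion of the weighted means across repeats.
#'
#' @slot pairwise data.frame with one row per class pair: `classA`,
#'   `classB`, `n`, `weight`, `BA`, `F1`, `AUROC`.
#' @slot weighted named numeric: weighted-mean `BA`, `F1`, `AUROC`.
#' @slot repeatSD named numeric: SD of the weighted means across repeats
#'   (NA when there is a single evaluation).
#' @slot perRepeat data.frame of weighted means per repeat (possibly empty).
#'
#' @seealso [pairwiseMetrics()], [nestedCVEvaluate()]
#' @exportClass MetricSet
setClass("MetricSet",
  representation(
    pairwise = "data.frame",
    weighted = "numeric",
    repeatSD = "numeric",
    perRepeat = "data.frame"
  )
)

#' Confounder-adjusted cross-correlation result
#'
#' Genus x metabolite matrix of partial Pearson correlations (residuals of
#' each variable on the confounders), with raw permutation p-values and
#' Westfall-Young step-down min-p adjusted p-values, and the highlight mask
#' of entries that are both significant after correction and above the
#' correlation threshold.
#'
#' @slot r,pRaw,pAdj numeric matrices (genera x metabolites).
#' @slot mask logical matrix: `pAdj < alpha & |r| > rHighlight`.
#' @slot confounders character vector of adjusting covariates.
#' @slot B integer, number of permutations (0 when p-values not computed).
#' @slot alpha,rHighlight thresholds used for the mask.
#' @slot seed integer permutation seed.
#'
#' @seealso [crossCorrMatrix()], [pminAdjust()], [crossCorrelate()]
#' @exportClass CrossCorrResult
setClass("CrossCorrResult",
  representation(
    r = "matrix",
    pRaw = "matrixOrNULL",
    pAdj = "matrixOrNULL",
    mask = "matrixOrNULL",
    confounders = "character",
    B = "integer",
    alpha = "numeric",
    rHighlight = "numeric",
    seed = "integer"
  )
)

setValidity("CrossCorrResult", function(object) {
  msg <- character()
  rr <- object@r[is.finite(object@r)]
  if (length(rr) && (max(rr) > 1 + 1e-8 || min(rr) < -1 - 1e-8))
    msg <- c(msg, "partial correlations must lie in [-1, 1]")
  if (!is.null(object@pRaw) && !is.null(object@pAdj)) {
    ok <- is.finite(object@pRaw) & is.finite(object@pAdj)
    if (any(object@pAdj[ok] < object@pRaw[ok] - 1e-12))
      msg <- c(msg, "adjusted p must be >= raw p")
  }
  if (length(msg)) msg else TRUE
})

#' Ward bi-clustering of a cross-correlation matrix
#'
#' Cluster assignments for genera (rows) and metabolites (columns) of a
#' partial-correlation matrix, the per-sample centroid tables (cluster means
#' of raw relative abundances / peak areas), and, once computed, the
#' simplified cross-correlation of the centroids.
#'
#' @slot genusClusters,metaboliteClusters named integer assignment vectors.
#' @slot genusTree,metaboliteTree `hclust` dendrograms.
#' @slot genusCentroids,metaboliteCentroids samples x cluster matrices
#'   (NULL until [centroidSimplifiedMatrix()] is run).
#' @slot simplified [CrossCorrResult-class] on the centroids, or NULL.
#'
#' @seealso [clusterBidirectional()], [centroidSimplifiedMatrix()]
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    genusClusters = "integer",
    metaboliteClusters = "integer",
    genusTree = "ANY",
    metaboliteTree = "ANY",
    genusCentroids = "matrixOrNULL",
    metaboliteCentroids = "matrixOrNULL",
    simplified = "ANY"
  )
)

#' FreeViz-style radial projection model
#'
#' Linear 2-D projection of standardized features whose per-feature anchor
#' vectors are optimized by class-dependent attractive/repulsive forces;
#' quality is summarized by the average silhouette of the embedding.
#'
#' @slot anchors features x 2 anchor matrix, max row norm 1.
#' @slot embedding samples x 2 projected coordinates.
#' @slot silhouette final average silhouette of the embedding.
#' @slot trace numeric vector, average silhouette per iteration.
#' @slot classEllipses list of per-class `list(center, cov)` summaries.
#' @slot seed integer seed.
#'
#' @seealso [freevizFit()], [avgSilhouette()]
#' @exportClass ProjectionModel
setClass("ProjectionModel",
  representation(
    anchors = "matrix",
    embedding = "matrix",
    silhouette = "numeric",
    trace = "numeric",
    classEllipses = "list",
    seed = "integer"
  )
)

#' Result of a repeated nested cross-validation run
#'
#' @slot metrics [MetricSet-class] aggregated across repeats.
#' @slot consensus character vector of features selected in more than half
#'   of the outer-fold models.
#' @slot selection logical matrix, outer cells x features.
#' @slot cells data.frame with one row per (repeat, fold): chosen learner,
#'   subset size, inner fitness.
#' @slot traces list of hill-climb trace data.frames, one per outer cell.
#' @slot features character, the post-filter feature universe.
#'
#' @seealso [nestedCVEvaluate()]
#' @exportClass NestedCVResult
setClass("NestedCVResult",
  representation(
    metrics = "MetricSet",
    consensus = "character",
    selection = "matrix",
    cells = "data.frame",
    traces = "list",
    features = "character"
  )
)
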