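#' @rdname MultiOmicCohort-class
#' @aliases abundances,MultiOmicCohort-method
setMethod("abundances", "MultiOmicCohort", function(x) x@abundance)

#' @rdname MultiOmicCohort-class
setMethod("peakAreas", "MultiOmicCohort", function(x) x@peaks)

#' @rdname MultiOmicCohort-class
setMethod("sampleData", "MultiOmicCohort", function(x) x@sampleData)

#' @rdname MultiOmicCohort-class
setMethod("plantedTruth", "MultiOmicCohort", function(x) x@truth)

#' @rdname MultiOmicCohort-class
setMethod("sampleGroups", "MultiOmicCohort", function(x) x@sampleData$group)

#' Confounder design matrix
#'
#' Returns the samples x 4 numeric matrix of adjusting covariates (age and
#' the three binary treatment flags) used throughout the cross-correlation
#' analysis.
#'
#' @rdname MultiOmicCohort-class
setMethod("confounderMatrix", "MultiOmicCohort", function(x) {
  md <- x@sampleData
  out <- cbind(
    age = md$age,
    hcq = as.numeric(md$hcq),
    prednisone_gt5 = as.numeric(md$prednisone_gt5),
    immunosuppressant = as.numeric(md$immunosuppressant)
  )
  rownames(out) <- rownames(md)
  out
})

setMethod("show", "MultiOmicCohort", function(object) {
  md <- object@sampleData
  cat("MultiOmicCohort:", nrow(object@abundance), "samples\n")
  cat("  abundance:", ncol(object@abundance), "genera (rows sum to 1)\n")
  cat("  peaks:    ", ncol(object@peaks), "metabolite peaks\n")
  tab <- table(md$group)
  cat("  groups:   ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (length(object@truth))
    cat("  truth:    ", length(object@truth$genera), "planted genera,",
        length(object@truth$peaks), "planted peaks,",
        length(object@truth$blocks), "correlation blocks\n")
  invisible(NULL)
})

#' @rdname FoldPlan-class
setMethod("foldCell", "FoldPlan", function(x, rep, fold) x@plan[[rep]][[fold]])

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@repeats, "repeats x", object@outerFolds,
      "outer folds (", object@innerFolds, "inner ), seed", object@seed, "\n")
  invisible(NULL)
})

#' @rdname MetricSet-class
setMethod("pairwiseTable", "MetricSet", function(x) x@pairwise)

#' @rdname MetricSet-class
setMethod("weightedMeans", "MetricSet", function(x) x@weighted)

setMethod("show", "MetricSet", function(object) {
  w <- object@weighted
  s <- object@repeatSD
  fmt <- function(m, sd) {
    if (is.finite(sd)) sprintf("%.3f +/- %.3f", m, sd) else sprintf("%.3f", m)
  }
  cat("MetricSet (weighted one-vs-one means over",
      nrow(object@pairwise), "class pairs)\n")
  cat("  BA:   ", fmt(w["BA"], s["BA"]), "\n")
  cat("  F1:   ", fmt(w["F1"], s["F1"]), "\n")
  cat("  AUROC:", fmt(w["AUROC"], s["AUROC"]), "\n")
  invisible(NULL)
})

#' @rdname CrossCorrResult-class
setMethod("partialR", "CrossCorrResult", function(x) x@r)

#' @rdname CrossCorrResult-class
setMethod("rawP", "CrossCorrResult", function(x) x@pRaw)

#' @rdname CrossCorrResult-class
setMethod("adjustedP", "CrossCorrResult", function(x) x@pAdj)

#' @rdname CrossCorrResult-class
setMethod("highlightMask", "CrossCorrResult", function(x) x@mask)

setMethod("show", "CrossCorrResult", function(object) {
  cat("CrossCorrResult:", nrow(object@r), "genera x", ncol(object@r),
      "metabolites\n")
  cat("  confounders:", if (length(object@confounders))
      paste(object@confounders, collapse = ", ") else "(none)", "\n")
  if (object@B > 0L) {
    cat("  permutations:", object@B, " highlight: adj p <", object@alpha,
        "& |r| >", object@rHighlight, "\n")
    cat("  highlighted entries:", sum(object@mask, na.rm = TRUE), "\n")
  } else {
    cat("  p-values: not computed\n")
  }
  invisible(NULL)
})

#' @rdname ClusterModel-class
setMethod("genusClusters", "ClusterModel", function(x) x@genusClusters)

#' @rdname ClusterModel-class
setMethod("metaboliteClusters", "ClusterModel", function(x) x@metaboliteClusters)

#' @rdname ClusterModel-class
setMethod("simplifiedResult", "ClusterModel", function(x) x@simplified)

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", max(object@genusClusters), "genus clusters /",
      max(object@metaboliteClusters), "metabolite clusters\n")
  cat("  simplified matrix:",
      if (is.null(object@simplified)) "not computed" else "computed", "\n")
  invisible(NULL)
})

setMethod("show", "ProjectionModel", function(object) {
  cat("ProjectionModel:", nrow(object@anchors), "anchors,",
      nrow(object@embedding), "samples, avg silhouette",
      sprintf("%.3f", object@silhouette), "\n")
  invisible(NULL)
})

#' @rdname NestedCVResult-class
setMethod("cvMetrics", "NestedCVResult", function(x) x@metrics)

#' @rdname NestedCVResult-class
setMethod("consensusFeatures", "NestedCVResult", function(x) x@consensus)

setMethod("show", "NestedCVResult", function(object) {
  cat("NestedCVResult over", nrow(object@selection), "outer models\n")
  show(object@metrics)
  cat("  consensus subset:", length(object@consensus), "of",
      length(object@features), "features\n")
  invisible(NULL)
})
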