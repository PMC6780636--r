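#' @rdname MultiOmicCohort-class
#' @param object,x a [MultiOmicCohort-class]
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname MultiOmicCohort-class
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname MultiOmicCohort-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname MultiOmicCohort-class
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname MultiOmicCohort-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname MultiOmicCohort-class
#' @export
setGeneric("confounderMatrix", function(x) standardGeneric("confounderMatrix"))

#' @rdname FoldPlan-class
#' @param x a [FoldPlan-class]
#' @param rep,fold repeat and outer-fold index
#' @export
setGeneric("foldCell", function(x, rep, fold) standardGeneric("foldCell"))

#' @rdname MetricSet-class
#' @param x a [MetricSet-class]
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))

#' @rdname MetricSet-class
#' @export
setGeneric("weightedMeans", function(x) standardGeneric("weightedMeans"))

#' @rdname CrossCorrResult-class
#' @param x a [CrossCorrResult-class]
#' @export
setGeneric("partialR", function(x) standardGeneric("partialR"))

#' @rdname CrossCorrResult-class
#' @export
setGeneric("rawP", function(x) standardGeneric("rawP"))

#' @rdname CrossCorrResult-class
#' @export
setGeneric("adjustedP", function(x) standardGeneric("adjustedP"))

#' @rdname CrossCorrResult-class
#' @export
setGeneric("highlightMask", function(x) standardGeneric("highlightMask"))

#' @rdname ClusterModel-class
#' @param x a [ClusterModel-class]
#' @export
setGeneric("genusClusters", function(x) standardGeneric("genusClusters"))

#' @rdname ClusterModel-class
#' @export
setGeneric("metaboliteClusters", function(x) standardGeneric("metaboliteClusters"))

#' @rdname ClusterModel-class
#' @export
setGeneric("simplifiedResult", function(x) standardGeneric("simplifiedResult"))

#' @rdname NestedCVResult-class
#' @param x a [NestedCVResult-class]
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname NestedCVResult-class
#' @export
setGeneric("consensusFeatures", function(x) standardGeneric("consensusFeatures"))
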