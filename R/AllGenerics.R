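#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes, so user code
#' never reaches into slots directly.
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("coreLabels", function(x) standardGeneric("coreLabels"))

#' @rdname accessors
#' @export
setGeneric("pointDensities", function(x) standardGeneric("pointDensities"))

#' @rdname accessors
#' @export
setGeneric("bandwidths", function(x) standardGeneric("bandwidths"))

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("relevantGenes", function(x) standardGeneric("relevantGenes"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("metricAggregates", function(x) standardGeneric("metricAggregates"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
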