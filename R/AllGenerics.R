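#' @rdname PPINetwork
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname PPINetwork
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname PPINetwork
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname PPINetwork
#' @export
setGeneric("numProteins", function(x) standardGeneric("numProteins"))

#' @rdname PPINetwork
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

#' @rdname DomainComposition
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname DDIPairSet
#' @export
setGeneric("ddiPairs", function(x) standardGeneric("ddiPairs"))

#' @rdname DDIPairSet
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname buildCandidatePairs
#' @export
setGeneric("supportMap", function(x) standardGeneric("supportMap"))

#' @rdname buildCandidatePairs
#' @export
setGeneric("edgeCandidates", function(x) standardGeneric("edgeCandidates"))

#' @rdname computeWeights
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname computeWeights
#' @export
setGeneric("prioritySet", function(x) standardGeneric("prioritySet"))

#' @rdname computeWeights
#' @export
setGeneric("prioritySetSize", function(x) standardGeneric("prioritySetSize"))

#' @rdname solveLP
#' @export
setGeneric("solutionValues", function(x) standardGeneric("solutionValues"))

#' @rdname solveLP
#' @export
setGeneric("slackValues", function(x) standardGeneric("slackValues"))

#' @rdname solveLP
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname solveLP
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname solveLP
#' @export
setGeneric("nFractional", function(x) standardGeneric("nFractional"))

#' @rdname NullDistribution
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname NullDistribution
#' @export
setGeneric("observedValue", function(x) standardGeneric("observedValue"))

#' @rdname NullDistribution
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
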