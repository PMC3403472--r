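#' Construct a PPI network
#'
#' Builds an undirected simple network from an edge table.  Edges are
#' canonicalized ((a, b) and (b, a) are the same edge), duplicate rows are
#' merged and self-interactions are dropped.
#'
#' @param edges two-column character matrix or data frame of protein pairs
#' @param proteins optional identifiers to include even when isolated;
#'   endpoints of `edges` are always included
#' @param metadata optional list attached to the object
#' @return a [PPINetwork-class]
#' @examples
#' net <- PPINetwork(cbind(c("P1", "P2"), c("P2", "P3")))
#' numEdges(net)
#' @export
PPINetwork <- function(edges = matrix(character(0), ncol = 2L),
                       proteins = NULL, metadata = list()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  mode(edges) <- "character"
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  edges <- .canonicalRows(edges)
  edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\t")), ,
    drop = FALSE]
  if (nrow(edges) > 0L)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  prot <- sort(unique(c(as.character(proteins), c(edges))))
  dimnames(edges) <- NULL
  new("PPINetwork", proteins = prot, edges = edges, metadata = metadata)
}

#' @param x a `PPINetwork`
#' @rdname PPINetwork
#' @export
setMethod("proteins", "PPINetwork", function(x) x@proteins)

#' @rdname PPINetwork
#' @export
setMethod("edges", "PPINetwork", function(x) x@edges)

#' @rdname PPINetwork
#' @export
setMethod("numEdges", "PPINetwork", function(x) nrow(x@edges))

#' @rdname PPINetwork
#' @export
setMethod("numProteins", "PPINetwork", function(x) length(x@proteins))

#' @rdname PPINetwork
#' @export
setMethod("loadReport", "PPINetwork", function(x) x@metadata$loadReport)

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", numProteins(object), "proteins and",
    numEdges(object), "edges\n")
})

# internal: canonical edge keys of a network
.edgeKeys <- function(net) {
  e <- edges(net)
  if (nrow(e) == 0L) character(0) else .pairKey(e[, 1L], e[, 2L])
}

# internal: convert to igraph, keeping isolated proteins
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(edges(net), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = proteins(net), stringsAsFactors = FALSE))
}

# internal: back-convert, preserving the vertex set
.fromIgraph <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  PPINetwork(el, proteins = igraph::V(g)$name)
}

#' Construct a domain composition
#'
#' @param assignments named list mapping each protein identifier to a
#'   character vector of domain identifiers; domains are deduplicated and
#'   sorted
#' @return a [DomainComposition-class]
#' @examples
#' comp <- DomainComposition(list(P1 = c("A", "B"), P2 = "A"))
#' @export
DomainComposition <- function(assignments = list()) {
  assignments <- lapply(assignments, function(d) sort(unique(as.character(d))))
  if (length(assignments) == 0L)
    assignments <- structure(list(), names = character(0))
  new("DomainComposition", assignments = assignments)
}

#' @param x a `DomainComposition`
#' @rdname DomainComposition
#' @export
setMethod("assignments", "DomainComposition", function(x) x@assignments)

setMethod("show", "DomainComposition", function(object) {
  cat("DomainComposition for", length(object@assignments), "proteins (",
    length(unique(unlist(object@assignments))), "distinct domains )\n")
})

#' Construct a DDI pair set
#'
#' @param pairs two-column character matrix or data frame of domain pairs;
#'   canonicalized and deduplicated.  Homodomain pairs (A, A) are retained.
#' @return a [DDIPairSet-class]
#' @examples
#' gold <- DDIPairSet(cbind(c("A", "B"), c("B", "A")))
#' nrow(ddiPairs(gold))  # 1
#' @export
DDIPairSet <- function(pairs = matrix(character(0), ncol = 2L)) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
  mode(pairs) <- "character"
  pairs <- .canonicalRows(pairs)
  pairs <- pairs[!duplicated(paste(pairs[, 1L], pairs[, 2L], sep = "\t")), ,
    drop = FALSE]
  if (nrow(pairs) > 0L)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- NULL
  new("DDIPairSet", pairs = pairs)
}

#' @param x a `DDIPairSet` (or `CandidateDDISet`)
#' @rdname DDIPairSet
#' @export
setMethod("ddiPairs", "DDIPairSet", function(x) x@pairs)

#' @rdname DDIPairSet
#' @export
setMethod("pairKeys", "DDIPairSet", function(x) {
  if (nrow(x@pairs) == 0L) character(0)
  else .pairKey(x@pairs[, 1L], x@pairs[, 2L])
})

setMethod("show", "DDIPairSet", function(object) {
  cat("DDIPairSet with", nrow(object@pairs), "domain pairs\n")
})

#' @rdname DDIPairSet
#' @export
setMethod("ddiPairs", "CandidateDDISet", function(x) x@pairs)

#' @rdname DDIPairSet
#' @export
setMethod("pairKeys", "CandidateDDISet", function(x) {
  if (nrow(x@pairs) == 0L) character(0)
  else .pairKey(x@pairs[, 1L], x@pairs[, 2L])
})

#' @rdname buildCandidatePairs
#' @export
setMethod("supportMap", "CandidateDDISet", function(x) x@support)

#' @rdname buildCandidatePairs
#' @export
setMethod("edgeCandidates", "CandidateDDISet", function(x) x@edgeCandidates)

setMethod("show", "CandidateDDISet", function(object) {
  cat("CandidateDDISet with", nrow(object@pairs), "candidate pairs over",
    length(object@edgeCandidates), "edges\n")
})

#' Construct a null distribution
#'
#' Summarizes samples of a statistic under a null model and computes the
#' Gaussian-tail p-value of the observed value (see [gaussianPValue()]).
#'
#' @param samples numeric statistic values under the null
#' @param observed the observed reference value
#' @param direction `"lower"` or `"upper"`: which tail is significant
#' @return a [NullDistribution-class]
#' @export
NullDistribution <- function(samples, observed, direction = "upper") {
  samples <- as.numeric(samples)
  p <- if (length(samples) >= 2L)
    gaussianPValue(observed, samples, direction) else NA_real_
  new("NullDistribution", samples = samples, observed = observed,
    direction = direction, pValue = p, nullMean = mean(samples),
    nullSD = stats::sd(samples), nullMedian = stats::median(samples))
}

#' @param x a `NullDistribution`
#' @rdname NullDistribution
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)

#' @rdname NullDistribution
#' @export
setMethod("observedValue", "NullDistribution", function(x) x@observed)

#' @rdname NullDistribution
#' @export
setMethod("pValue", "NullDistribution", function(x) x@pValue)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d samples, mean %.6g, sd %.6g, median %.6g\n",
    length(object@samples), object@nullMean, object@nullSD,
    object@nullMedian))
  cat(sprintf("  observed %.6g, %s-tail p-value %s\n", object@observed,
    object@direction,
    if (is.na(object@pValue)) "undefined (sd = 0)"
    else format(object@pValue, digits = 4)))
})

setMethod("show", "RandomizationTestResult", function(object) {
  cat(sprintf("RandomizationTestResult [%s], statistic %s\n", object@mode,
    object@statisticName))
  cat(sprintf("  observed %s0 = %.6g over %d shuffles\n",
    object@statisticName, object@observed, object@nShuffles))
  show(object@null)
})

setMethod("show", "LoadReport", function(object) {
  cat("LoadReport: ", object@rowsRead, " rows read, ",
    object@selfLoopsDropped, " self-interactions dropped, ",
    object@duplicateEdgesMerged, " duplicates merged, ",
    object@proteinsWithoutComposition, " proteins without composition\n",
    sep = "")
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: %d predictions, %d true positives (gold in D: %d, |D|: %d)\n",
    object@totalPredictions, object@truePositives, object@goldInCandidates,
    object@candidateSize))
  cat(sprintf("  sensitivity %.2f%%, fold change %.2f\n",
    100 * object@sensitivity, object@foldChange))
})
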