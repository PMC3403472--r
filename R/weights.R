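# Network-derived candidate weights: interactions that close a triangle
# through a poor (bin-1) protein are prioritized for explanation by DDIs.

#' Compute candidate weights from degree binning
#'
#' Degrees are binned into K equal-width subintervals
#' ([degreeBinning()]).  An observed interaction (P_m, P_n) belongs to the
#' priority structure when some bin-1 ("poor") protein is adjacent to both
#' endpoints, i.e. the interaction closes a triangle through a poor node
#' -- the configuration that gives real PPI networks their large
#' clustering coefficient.  Candidate pairs of such an interaction
#' receive weight 1 / (1 + |s - t|), with s, t the degree bins of P_m and
#' P_n, so disassortative interactions (large bin gap) are discounted
#' most.  A pair supported by several priority interactions takes the
#' smallest weight; pairs outside the priority set S keep weight 1.
#'
#' @param network a harmonized [PPINetwork-class]
#' @param composition the matching [DomainComposition-class]
#' @param candidates the [CandidateDDISet-class] of the network
#' @param K number of degree bins (>= 1)
#' @return a [WeightMap-class]; `prioritySetSize(x)` is |S|
#' @export
computeWeights <- function(network, composition, candidates, K) {
  stopifnot(is(network, "PPINetwork"), is(candidates, "CandidateDDISet"))
  bins <- degreeBinning(network, K)@assignment
  e <- edges(network)
  ekeys <- .edgeKeys(network)
  # adjacency list
  nbr <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
  edgeSet <- structure(seq_along(ekeys), names = ekeys)
  # edges that close a triangle through a poor node
  poor <- names(bins)[bins == 1L]
  triEdge <- character(0)
  for (p in poor) {
    np <- nbr[[p]]
    if (length(np) < 2L) next
    cmb <- combn(sort(np), 2L)
    k <- .pairKey(cmb[1L, ], cmb[2L, ])
    triEdge <- c(triEdge, k[k %in% names(edgeSet)])
  }
  triEdge <- unique(triEdge)
  ends <- .splitKeys(triEdge)
  ew <- if (length(triEdge) > 0L)
    setNames(1 / (1 + abs(bins[ends[, 1L]] - bins[ends[, 2L]])), triEdge)
  else setNames(numeric(0), character(0))
  keys <- pairKeys(candidates)
  w <- setNames(rep(1, length(keys)), keys)
  sup <- supportMap(candidates)
  inS <- vapply(keys, function(k) any(sup[[k]] %in% triEdge), logical(1))
  w[inS] <- vapply(keys[inS], function(k)
    min(ew[intersect(sup[[k]], triEdge)]), numeric(1))
  new("WeightMap", weights = w, prioritySet = keys[inS])
}

#' @param x a `WeightMap`
#' @rdname computeWeights
#' @export
setMethod("weightValues", "WeightMap", function(x) x@weights)

#' @rdname computeWeights
#' @export
setMethod("prioritySet", "WeightMap", function(x) x@prioritySet)

#' @rdname computeWeights
#' @export
setMethod("prioritySetSize", "WeightMap", function(x)
  length(x@prioritySet))

setMethod("show", "WeightMap", function(object) {
  cat("WeightMap over", length(object@weights), "candidate pairs; |S| =",
    length(object@prioritySet), "\n")
})
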