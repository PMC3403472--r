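# Candidate DDI construction and witness counting.

#' Build the candidate DDI set D
#'
#' For every observed interaction (P_m, P_n), the candidate pairs are all
#' unordered domain pairs (i, j) with i in the composition of one endpoint
#' and j in the other (both orientations; homodomain pairs included).  D
#' is the union over edges, with, for each pair, the set of supporting
#' edges.
#'
#' @param network a harmonized [PPINetwork-class]
#' @param composition a [DomainComposition-class] covering every edge
#'   endpoint
#' @return a [CandidateDDISet-class]
#' @examples
#' net <- PPINetwork(cbind(c("P1", "P2", "P3"), c("P2", "P3", "P4")))
#' comp <- DomainComposition(list(P1 = "A", P2 = "B", P3 = "A", P4 = "C"))
#' cand <- buildCandidatePairs(net, comp)
#' pairKeys(cand)
#' @export
buildCandidatePairs <- function(network, composition) {
  stopifnot(is(network, "PPINetwork"), is(composition, "DomainComposition"))
  e <- edges(network)
  asg <- assignments(composition)
  missing <- setdiff(unique(c(e)), names(asg))
  if (length(missing) > 0L)
    stop("edge endpoints without composition (harmonize first): ",
      paste(head(missing, 3L), collapse = ", "))
  ekeys <- .edgeKeys(network)
  edgeCand <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    di <- asg[[e[k, 1L]]]
    dj <- asg[[e[k, 2L]]]
    edgeCand[[k]] <- unique(as.vector(outer(di, dj, .pairKey)))
  }
  names(edgeCand) <- ekeys
  allKeys <- sort(unique(unlist(edgeCand)))
  support <- split(rep(ekeys, lengths(edgeCand)),
    factor(unlist(edgeCand), levels = allKeys))
  new("CandidateDDISet", pairs = .splitKeys(allKeys),
    support = support, edgeCandidates = edgeCand)
}

#' Count witnesses of candidate pairs
#'
#' A witness of a domain pair (i, j) is an interacting pair of
#' single-domain proteins whose domains are i and j: direct evidence not
#' attributable to any other pair.  The term (1 - r)^w(i,j) in the
#' pw-score is the probability that all witness interactions are false
#' positives at reliability r.
#'
#' @inheritParams buildCandidatePairs
#' @param candidates optional [CandidateDDISet-class]; when supplied the
#'   returned vector covers all its pairs (zeros included)
#' @return named integer vector of witness counts by pair key
#' @export
countWitnesses <- function(network, composition, candidates = NULL) {
  stopifnot(is(network, "PPINetwork"), is(composition, "DomainComposition"))
  e <- edges(network)
  asg <- assignments(composition)
  single <- names(asg)[lengths(asg) == 1L]
  both <- e[, 1L] %in% single & e[, 2L] %in% single
  keys <- if (any(both)) {
    d1 <- vapply(asg[e[both, 1L]], `[[`, character(1), 1L)
    d2 <- vapply(asg[e[both, 2L]], `[[`, character(1), 1L)
    .pairKey(d1, d2)
  } else character(0)
  counts <- table(keys)
  out <- setNames(as.integer(counts), names(counts))
  if (!is.null(candidates)) {
    full <- setNames(integer(length(pairKeys(candidates))),
      pairKeys(candidates))
    full[intersect(names(out), names(full))] <-
      out[intersect(names(out), names(full))]
    out <- full
  }
  out
}
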