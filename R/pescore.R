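# Reliability-sampled LP-scores, randomization p-values and pw-scores
# for the pure parsimony-explanation (PE) cover model.

#' Reliability-sampled LP-score
#'
#' Models noise in the interaction data by keeping each cover constraint
#' independently with probability `r` (the reliability), solving the pure
#' cover LP on the kept constraints, and averaging each pair's LP value
#' over `nRuns` repetitions.  With `r = 1` every run is the full PE
#' solution and the score is deterministic.
#'
#' @param candidates a [CandidateDDISet-class]
#' @param network the matching [PPINetwork-class]
#' @param r reliability probability in (0, 1]
#' @param nRuns number of constraint subsamples (1000 in typical use)
#' @param seed optional RNG seed
#' @return named numeric vector: pair key -> average LP value in \[0, 1\]
#' @export
lpScore <- function(candidates, network, r, nRuns = 1000L, seed = NULL) {
  stopifnot(is(candidates, "CandidateDDISet"))
  if (!is.numeric(r) || r <= 0 || r > 1)
    stop("reliability r must lie in (0, 1]")
  nRuns <- as.integer(nRuns)
  if (nRuns < 1L) stop("nRuns must be >= 1")
  ekeys <- names(edgeCandidates(candidates))
  if (r == 1) {
    return(.solvePE(candidates)$values)
  }
  .withSeed(seed, {
    acc <- setNames(rep(0, length(pairKeys(candidates))),
      pairKeys(candidates))
    for (run in seq_len(nRuns)) {
      keep <- ekeys[runif(length(ekeys)) <= r]
      acc <- acc + .solvePE(candidates, keep)$values
    }
    acc / nRuns
  })
}

#' Empirical p-values against degree-preserving random networks
#'
#' Significance of each pair's LP-score against an ensemble of
#' degree-preserving rewirings of the input network (compositions are
#' kept fixed, so the domain content of each protein is unchanged while
#' the interaction structure is randomized).  The p-value of a pair is
#' the fraction of reference networks whose LP-score for that pair is at
#' least the observed one; pairs absent from a reference candidate set
#' contribute score 0.
#'
#' @inheritParams lpScore
#' @param composition the [DomainComposition-class] (held fixed)
#' @param nNetworks number of reference networks (1000 in typical use)
#' @param nRuns constraint subsamples per LP-score evaluation
#' @return named numeric vector of p-values in \[0, 1\] over the observed
#'   candidate pairs
#' @export
empiricalPValues <- function(candidates, network, composition, r,
                             nNetworks = 1000L, nRuns = 10L, seed = NULL) {
  stopifnot(is(network, "PPINetwork"), is(composition, "DomainComposition"))
  nNetworks <- as.integer(nNetworks)
  if (nNetworks < 1L) stop("nNetworks must be >= 1")
  .withSeed(seed, {
    observed <- lpScore(candidates, network, r, nRuns, seed = NULL)
    hits <- setNames(rep(0L, length(observed)), names(observed))
    for (k in seq_len(nNetworks)) {
      ref <- rewirePreservingDegrees(network)
      refCand <- buildCandidatePairs(ref, composition)
      refScore <- lpScore(refCand, ref, r, nRuns, seed = NULL)
      sc <- refScore[names(observed)]
      sc[is.na(sc)] <- 0
      hits <- hits + as.integer(sc >= observed - 1e-12)
    }
    hits / nNetworks
  })
}

#' Combined pw-score
#'
#' `pw = min(p-value, (1 - r)^w)`: the randomization p-value capped by
#' the probability that all witness interactions of the pair are false
#' positives at reliability r (with `(1 - r)^0 = 1`).  The witness term
#' demotes promiscuous pairs that score high only through their
#' frequency.
#'
#' @param lpScores named LP-score vector (defines the key set)
#' @param pValues named p-value vector over the same keys
#' @param witnesses named integer witness counts over the same keys
#' @param r the reliability used for the LP-scores
#' @return named numeric vector of pw-scores
#' @export
pwScore <- function(lpScores, pValues, witnesses, r) {
  keys <- names(lpScores)
  if (!setequal(keys, names(pValues)) || !setequal(keys, names(witnesses)))
    stop("lpScores, pValues and witnesses must share one key set")
  setNames(pmin(pValues[keys], (1 - r)^witnesses[keys]), keys)
}
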