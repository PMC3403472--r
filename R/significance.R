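# Randomization tests: the two parsimony shuffles (is the observed
# minimal DDI count smaller than under a null with no parsimonious
# organization?) and the random-weight significance test.

#' Shuffle domain compositions, conserving per-protein counts
#'
#' Permutes the global multiset of domain assignments across protein
#' slots: each protein keeps its original number of domains and the
#' global domain multiset is conserved, but which protein carries which
#' domain is randomized.  Permutations that would place two copies of a
#' domain in one protein are rejected and redrawn, so the result is a
#' valid composition of sets.
#'
#' @param composition a non-empty [DomainComposition-class]
#' @param seed optional RNG seed
#' @return a shuffled [DomainComposition-class]
#' @export
shuffleDomainComposition <- function(composition, seed = NULL) {
  stopifnot(is(composition, "DomainComposition"))
  asg <- assignments(composition)
  if (length(asg) == 0L) stop("composition is empty")
  sizes <- lengths(asg)
  tokens <- unlist(asg, use.names = FALSE)
  grp <- rep(seq_along(asg), sizes)
  .withSeed(seed, {
    for (try in seq_len(10000L)) {
      perm <- sample(tokens)
      dup <- vapply(split(perm, grp), anyDuplicated, integer(1)) > 0L
      if (!any(dup)) {
        return(DomainComposition(setNames(split(perm, grp)[
          as.character(seq_along(asg))], names(asg))))
      }
    }
    stop("could not find a duplicate-free shuffle in 10000 draws")
  })
}

#' Shuffle edges, conserving the degree sequence
#'
#' Randomizes the interactions while maintaining each protein's
#' composition and degree, by degree-preserving double-edge swaps
#' ([rewirePreservingDegrees()]).
#'
#' @param network a [PPINetwork-class] with >= 2 edges
#' @param seed optional RNG seed
#' @return a rewired [PPINetwork-class]
#' @export
shuffleEdges <- function(network, seed = NULL) {
  rewirePreservingDegrees(network, swapMultiplier = 10, seed = seed)
}

#' Randomization test of the parsimony assumption
#'
#' Computes T0, the minimal number of DDIs explaining all observed
#' interactions (the pure cover optimum), and compares it with the
#' distribution of the same statistic T on shuffled data: either the
#' compositions are shuffled with the network conserved, or the edges are
#' rewired with the compositions conserved.  If interactions really are
#' organized parsimoniously -- few domain pair types reused across many
#' interactions -- T0 should fall far below the null, so the p-value is
#' the Gaussian lower tail of T0 against the T samples.
#'
#' @param network a harmonized [PPINetwork-class]
#' @param composition the matching [DomainComposition-class]
#' @param mode `"shuffle_compositions"` or `"shuffle_edges"`
#' @param nShuffles number of shuffled datasets (200 in typical use)
#' @param seed optional RNG seed
#' @return a [RandomizationTestResult-class] with statistic "T"
#' @export
parsimonyRandomizationTest <- function(network, composition,
    mode = c("shuffle_compositions", "shuffle_edges"), nShuffles = 200L,
    seed = NULL) {
  mode <- match.arg(mode)
  nShuffles <- as.integer(nShuffles)
  if (nShuffles < 2L) stop("nShuffles must be >= 2")
  cand0 <- buildCandidatePairs(network, composition)
  T0 <- .solvePE(cand0)$objective
  samples <- .withSeed(seed, vapply(seq_len(nShuffles), function(k) {
    if (mode == "shuffle_compositions") {
      compK <- shuffleDomainComposition(composition)
      netK <- harmonize(network, compK)
    } else {
      netK <- harmonize(shuffleEdges(network), composition)
      compK <- composition
    }
    .solvePE(buildCandidatePairs(netK, compK))$objective
  }, numeric(1)))
  new("RandomizationTestResult", statisticName = "T", observed = T0,
    null = NullDistribution(samples, T0, direction = "lower"),
    mode = mode, nShuffles = nShuffles,
    seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Random-weight significance test for the weighted model
#'
#' Asks whether the network-derived weights carry signal: the weighted
#' cover model is solved once with the true triangle/binning weights and
#' repeatedly with null weights -- a uniformly chosen subset of candidate
#' pairs, of the same size as the true priority set S, receives
#' i.i.d. Uniform(0, 0.5) weights while all other pairs keep weight 1.
#' The statistic is TP, the number of predictions confirmed by the gold
#' standard; the p-value is the Gaussian upper tail of the true-weight TP
#' against the null TP distribution.
#'
#' @inheritParams parsimonyRandomizationTest
#' @param gold the gold-standard [DDIPairSet-class]
#' @param sd slack parameter of the weighted model
#' @param K number of degree bins for the true weights
#' @param nRuns number of random-weight draws (500 in typical use)
#' @return a [RandomizationTestResult-class] with statistic "TP"
#' @export
randomWeightTest <- function(network, composition, gold, sd, K,
                             nRuns = 500L, seed = NULL) {
  stopifnot(is(gold, "DDIPairSet"))
  nRuns <- as.integer(nRuns)
  if (nRuns < 2L) stop("nRuns must be >= 2")
  if (sd <= 0 || sd > 1) stop("sd must lie in (0, 1]")
  cand <- buildCandidatePairs(network, composition)
  wmap <- computeWeights(network, composition, cand, K)
  nS <- prioritySetSize(wmap)
  if (nS == 0L)
    stop("no priority pairs exist at K = ", K,
      ": every triangle-closing weight is absent; increase K or check ",
      "the network for triangles through poor nodes")
  goldKeys <- pairKeys(gold)
  tpOf <- function(weights) {
    sol <- solveLP(buildLP(cand, network, sd, weights))
    length(intersect(pairKeys(roundPredictions(sol)), goldKeys))
  }
  tpTrue <- tpOf(wmap)
  keys <- pairKeys(cand)
  samples <- .withSeed(seed, vapply(seq_len(nRuns), function(k) {
    w <- setNames(rep(1, length(keys)), keys)
    pick <- sample(keys, nS)
    w[pick] <- runif(nS, 0, 0.5)
    tpOf(w)
  }, numeric(1)))
  new("RandomizationTestResult", statisticName = "TP",
    observed = as.numeric(tpTrue),
    null = NullDistribution(samples, tpTrue, direction = "upper"),
    mode = "random_weights", nShuffles = nRuns,
    seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Gaussian-tail p-value of an observed value against samples
#'
#' Fits a Gaussian to the samples (sample mean, n - 1 standard
#' deviation) and returns the tail probability of the observed value:
#' `pnorm(z)` for the lower tail, `1 - pnorm(z)` for the upper, with
#' `z = (observed - mean) / sd`.  Returns NA (undefined) when the sample
#' standard deviation is zero.
#'
#' @param observed the observed value
#' @param samples numeric vector of >= 2 null samples
#' @param direction `"lower"` or `"upper"`
#' @return a probability in \[0, 1\], or NA
#' @export
gaussianPValue <- function(observed, samples,
                           direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (length(samples) < 2L) stop("need at least 2 samples")
  s <- stats::sd(samples)
  if (s == 0) {
    warning("null samples are constant; p-value undefined")
    return(NA_real_)
  }
  z <- (observed - mean(samples)) / s
  if (direction == "lower") pnorm(z) else pnorm(z, lower.tail = FALSE)
}
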