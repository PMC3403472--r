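#' Load report for delimited-text inputs
#'
#' Bookkeeping counts produced by the readers and by [harmonize()]: rows
#' read, self-interactions dropped, duplicate rows merged, and proteins
#' excluded for lacking a domain composition.
#'
#' @slot rowsRead number of non-comment, non-blank rows read
#' @slot selfLoopsDropped self-interactions (P, P) removed at load
#' @slot duplicateEdgesMerged duplicate rows merged into one edge
#' @slot proteinsWithoutComposition proteins removed by [harmonize()]
#' @exportClass LoadReport
setClass("LoadReport",
  representation(rowsRead = "integer", selfLoopsDropped = "integer",
    duplicateEdgesMerged = "integer", proteinsWithoutComposition = "integer"),
  prototype(rowsRead = 0L, selfLoopsDropped = 0L,
    duplicateEdgesMerged = 0L, proteinsWithoutComposition = 0L),
  validity = function(object) {
    counts <- c(object@rowsRead, object@selfLoopsDropped,
      object@duplicateEdgesMerged, object@proteinsWithoutComposition)
    if (any(counts < 0L)) "all counts must be >= 0" else TRUE
  })

#' Undirected simple protein-protein interaction network
#'
#' Houses the observed network I = (P, E): a set of protein identifiers and
#' a set of unordered, canonicalized protein pairs.  Self-interactions are
#' not representable; the readers drop and count them.
#'
#' @slot proteins character vector of protein identifiers (may include
#'   proteins with no incident edge)
#' @slot edges two-column character matrix; each row is one edge with the
#'   lexicographically smaller identifier first; rows are unique
#' @slot metadata list; carries the [LoadReport-class] under
#'   `$loadReport` when produced by a reader
#' @exportClass PPINetwork
setClass("PPINetwork",
  representation(proteins = "character", edges = "matrix",
    metadata = "list"),
  prototype(proteins = character(0),
    edges = matrix(character(0), ncol = 2L), metadata = list()),
  validity = function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) > 0L) {
      if (any(e[, 1L] == e[, 2L])) return("self-interactions are not allowed")
      if (any(e[, 1L] > e[, 2L])) return("edges must be canonicalized")
      if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\t")) > 0L)
        return("duplicate edges")
      if (!all(c(e) %in% object@proteins))
        return("every edge endpoint must be a listed protein")
    }
    if (anyDuplicated(object@proteins) > 0L) return("duplicate proteins")
    TRUE
  })

#' Protein domain composition
#'
#' Maps each protein identifier to its non-empty set of constituent domain
#' identifiers.  Domain sets are deduplicated: copy number within a protein
#' cannot change which candidate domain pairs exist.
#'
#' @slot assignments named list; each element a sorted character vector of
#'   distinct domain identifiers
#' @exportClass DomainComposition
setClass("DomainComposition",
  representation(assignments = "list"),
  prototype(assignments = structure(list(), names = character(0))),
  validity = function(object) {
    a <- object@assignments
    if (length(a) == 0L) return(TRUE)
    if (is.null(names(a)) || any(!nzchar(names(a))))
      return("every protein key must be a non-empty string")
    if (anyDuplicated(names(a)) > 0L) return("duplicate protein keys")
    ok <- vapply(a, function(d)
      is.character(d) && length(d) > 0L && anyDuplicated(d) == 0L,
      logical(1))
    if (!all(ok)) return("domain sets must be non-empty and deduplicated")
    TRUE
  })

#' Set of unordered domain pairs
#'
#' A deduplicated set of domain-identifier pairs, canonicalized so the
#' lexicographically smaller identifier comes first.  Homodomain pairs
#' (A, A) are legal DDIs and are retained.
#'
#' @slot pairs two-column character matrix of canonical pairs
#' @exportClass DDIPairSet
setClass("DDIPairSet",
  representation(pairs = "matrix"),
  prototype(pairs = matrix(character(0), ncol = 2L)),
  validity = function(object) {
    p <- object@pairs
    if (ncol(p) != 2L) return("pairs must have two columns")
    if (nrow(p) > 0L) {
      if (any(p[, 1L] > p[, 2L])) return("pairs must be canonicalized")
      if (anyDuplicated(paste(p[, 1L], p[, 2L], sep = "\t")) > 0L)
        return("duplicate pairs")
    }
    TRUE
  })

#' Candidate DDI set with supporting edges
#'
#' The set D of unordered domain pairs occurring across the observed
#' interactions, with, for every pair, the set of network edges whose
#' endpoint compositions contain the pair, and the reverse map from each
#' edge to its candidate pairs.
#'
#' @slot pairs two-column character matrix of canonical candidate pairs
#' @slot support named list: pair key -> character vector of edge keys
#' @slot edgeCandidates named list: edge key -> character vector of pair keys
#' @exportClass CandidateDDISet
setClass("CandidateDDISet",
  representation(pairs = "matrix", support = "list",
    edgeCandidates = "list"),
  validity = function(object) {
    keys <- .pairKey(object@pairs[, 1L], object@pairs[, 2L])
    if (!setequal(keys, names(object@support)))
      return("support keys must match the candidate pairs")
    if (any(lengths(object@edgeCandidates) == 0L))
      return("every annotated edge must have at least one candidate pair")
    TRUE
  })

#' Degree binning of a network into K subintervals
#'
#' Partition of the degree range \[d_min, d_max\] into K equal-width
#' subintervals; bin 1 holds the low-degree ("poor") proteins and bin K the
#' hubs.
#'
#' @slot K number of subintervals
#' @slot binEdges K + 1 ascending degree values delimiting the bins
#' @slot assignment named integer vector: protein -> bin index in 1..K
#' @exportClass DegreeBinning
setClass("DegreeBinning",
  representation(K = "integer", binEdges = "numeric",
    assignment = "integer"),
  validity = function(object) {
    if (object@K < 1L) return("K must be >= 1")
    if (length(object@binEdges) != object@K + 1L)
      return("binEdges must have K + 1 values")
    if (is.unsorted(object@binEdges)) return("binEdges must be ascending")
    if (length(object@assignment) > 0L &&
        (any(object@assignment < 1L) || any(object@assignment > object@K)))
      return("bin indices must lie in 1..K")
    TRUE
  })

#' Candidate-pair weight map
#'
#' Weights w_ij in (0, 1] for the weighted cover model.  Pairs in the
#' priority set S -- pairs belonging to an observed interaction between two
#' neighbors of a poor (bin-1) protein -- receive 1 / (1 + |s - t|), where
#' s and t are the degree bins of the interacting proteins; all other pairs
#' have weight 1.
#'
#' @slot weights named numeric vector over candidate pair keys
#' @slot prioritySet character vector of pair keys in S
#' @exportClass WeightMap
setClass("WeightMap",
  representation(weights = "numeric", prioritySet = "character"),
  validity = function(object) {
    w <- object@weights
    if (length(w) > 0L && (any(w <= 0) || any(w > 1)))
      return("weights must lie in (0, 1]")
    if (!all(object@prioritySet %in% names(w)))
      return("priority set must index the weight map")
    if (length(w) > 0L && any(w[setdiff(names(w), object@prioritySet)] != 1))
      return("pairs outside S must have weight 1")
    TRUE
  })

#' Linear program for a cover model
#'
#' The LP relaxation of the (weighted) slack-budgeted cover model: one
#' variable d_ij per candidate pair and one slack e_mn per edge, one cover
#' constraint per edge, and the budget constraint
#' sum(e_mn) <= (1 - sd) |E|.  All variables are bounded in \[0, 1\].
#'
#' @slot obj objective coefficients (pair weights, then zeros for slacks)
#' @slot mat dense constraint matrix (cover rows, then the budget row)
#' @slot rhs right-hand sides
#' @slot dir row senses: +1 for >=, -1 for <=
#' @slot pairKeys,edgeKeys variable names in column order
#' @slot sd fraction of interactions that must be explained
#' @exportClass LPProblem
setClass("LPProblem",
  representation(obj = "numeric", mat = "matrix", rhs = "numeric",
    dir = "integer", pairKeys = "character", edgeKeys = "character",
    sd = "numeric"),
  validity = function(object) {
    if (object@sd < 0 || object@sd > 1) return("sd must lie in [0, 1]")
    n <- length(object@pairKeys) + length(object@edgeKeys)
    if (ncol(object@mat) != n) return("matrix width must match variables")
    if (nrow(object@mat) != length(object@rhs))
      return("matrix height must match rhs")
    TRUE
  })

#' Solution of a relaxed cover model
#'
#' Optimal LP-relaxation values for the pair variables d_ij and slack
#' variables e_mn, with the objective, the solver status, and the number of
#' variables strictly inside (tol, 1 - tol) -- the simplex returns vertex
#' solutions, which are almost always integral on realistic instances.
#'
#' @slot values named numeric: pair key -> value in \[0, 1\]
#' @slot slackValues named numeric: edge key -> value in \[0, 1\]
#' @slot objective optimal objective value
#' @slot solverStatus "optimal", "infeasible" or "error"
#' @slot nFractional count of variables strictly inside (1e-6, 1 - 1e-6)
#' @exportClass ParsimonySolution
setClass("ParsimonySolution",
  representation(values = "numeric", slackValues = "numeric",
    objective = "numeric", solverStatus = "character",
    nFractional = "integer"))

#' Null distribution of a network statistic
#'
#' Samples of a statistic under a null model, summarized with a
#' Gaussian-tail p-value against an observed value.  When the sample
#' standard deviation is zero the p-value is undefined and stored as NA.
#'
#' @slot samples statistic values under the null
#' @slot observed the reference value
#' @slot direction "lower" or "upper" tail
#' @slot pValue Gaussian-tail probability (NA when undefined)
#' @slot nullMean,nullSD,nullMedian sample summaries
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(samples = "numeric", observed = "numeric",
    direction = "character", pValue = "numeric", nullMean = "numeric",
    nullSD = "numeric", nullMedian = "numeric"),
  validity = function(object) {
    if (!object@direction %in% c("lower", "upper"))
      return("direction must be 'lower' or 'upper'")
    if (length(object@samples) > 0L) {
      if (object@nullMedian < min(object@samples) - 1e-12 ||
          object@nullMedian > max(object@samples) + 1e-12)
        return("median must lie within the sample range")
    }
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("p-value must lie in [0, 1]")
    TRUE
  })

#' Result of a randomization test
#'
#' Observed statistic (the parsimony optimum T0, or the true-weight TP)
#' together with its null distribution under a shuffle or random-weight
#' null model.
#'
#' @slot statisticName "T" or "TP"
#' @slot observed the observed value (T0 or true-weight TP)
#' @slot null a [NullDistribution-class]
#' @slot mode "shuffle_compositions", "shuffle_edges" or "random_weights"
#' @slot nShuffles number of null samples
#' @slot seed seed used (NA if none supplied)
#' @exportClass RandomizationTestResult
setClass("RandomizationTestResult",
  representation(statisticName = "character", observed = "numeric",
    null = "NullDistribution", mode = "character", nShuffles = "integer",
    seed = "numeric"),
  validity = function(object) {
    if (length(object@null@samples) != object@nShuffles)
      return("null sample count must equal nShuffles")
    TRUE
  })

#' Evaluation of predictions against a gold standard
#'
#' Counts and the derived sensitivity and fold change.  Sensitivity is
#' TP / |gold in candidates|; fold change is the prediction precision
#' divided by the gold density within the candidate set.
#'
#' @slot totalPredictions,truePositives,goldInCandidates,candidateSize counts
#' @slot sensitivity fraction in \[0, 1\] (NA when no gold pair is a
#'   candidate)
#' @slot foldChange ratio >= 0 (0, with a warning, when nothing is
#'   predicted)
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(totalPredictions = "integer", truePositives = "integer",
    goldInCandidates = "integer", candidateSize = "integer",
    sensitivity = "numeric", foldChange = "numeric"),
  validity = function(object) {
    if (object@truePositives >
        min(object@totalPredictions, object@goldInCandidates))
      return("TP cannot exceed predictions or gold-in-candidates")
    TRUE
  })

#' Specification for a synthetic PPI + composition dataset
#'
#' Study conditions for the generator: protein and domain universe sizes,
#' the mean number of domains per protein, the density of planted DDIs, the
#' target mean degree, false-positive/false-negative edge noise, and the
#' fraction of poor-node wedges closed by true edges (triangle enrichment).
#'
#' @slot nProteins,nDomains universe sizes
#' @slot domainsPerProtein mean of the 1 + geometric domain-count model
#' @slot plantedDDIDensity fraction of domain pairs that truly interact
#' @slot meanDegree target mean degree of the network
#' @slot fpRate fraction of spurious edges added
#' @slot fnRate fraction of true edges removed
#' @slot triangleBoost fraction of closable poor-node wedges closed
#' @slot seed generator seed
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nProteins = "integer", nDomains = "integer",
    domainsPerProtein = "numeric", plantedDDIDensity = "numeric",
    meanDegree = "numeric", fpRate = "numeric", fnRate = "numeric",
    triangleBoost = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@nProteins < 1L || object@nDomains < 1L)
      return("counts must be >= 1")
    fr <- c(object@plantedDDIDensity, object@fpRate, object@fnRate,
      object@triangleBoost)
    if (any(fr < 0) || any(fr > 1)) return("fractions must lie in [0, 1]")
    if (object@domainsPerProtein < 1) return("domainsPerProtein must be >= 1")
    TRUE
  })

#' Synthetic dataset with planted DDIs
#'
#' @slot network the generated [PPINetwork-class]
#' @slot composition the generated [DomainComposition-class]
#' @slot planted the planted gold-standard [DDIPairSet-class]
#' @slot trueEdges edge keys of edges explainable by a planted pair
#' @slot spec the generating [SyntheticSpec-class]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(network = "PPINetwork",
    composition = "DomainComposition", planted = "DDIPairSet",
    trueEdges = "character", spec = "SyntheticSpec"))
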