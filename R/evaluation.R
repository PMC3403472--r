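# Sensitivity and fold-change scoring against a gold standard, and the
# sd sweep comparing the weighted and unweighted models.

#' Evaluate counts into sensitivity and fold change
#'
#' Sensitivity is TP divided by the number of gold pairs that are
#' candidates (gold pairs outside the candidate set can never be
#' predicted and are excluded).  Fold change is the prediction precision
#' relative to the gold density of the candidate set:
#' `(TP / total) / (goldInCandidates / candidateSize)`, so predicting all
#' candidates gives fold change exactly 1.
#'
#' @param totalPredictions,truePositives,goldInCandidates,candidateSize
#'   the four counts
#' @return an [EvaluationResult-class]
#' @export
evaluationFromCounts <- function(totalPredictions, truePositives,
                                 goldInCandidates, candidateSize) {
  total <- as.integer(totalPredictions)
  tp <- as.integer(truePositives)
  gic <- as.integer(goldInCandidates)
  cs <- as.integer(candidateSize)
  sens <- if (gic > 0L) tp / gic else NA_real_
  if (gic == 0L) warning("no gold pair is a candidate; sensitivity undefined")
  fc <- if (total > 0L) (tp / total) / (gic / cs) else {
    warning("no predictions; fold change reported as 0")
    0
  }
  new("EvaluationResult", totalPredictions = total, truePositives = tp,
    goldInCandidates = gic, candidateSize = cs, sensitivity = sens,
    foldChange = fc)
}

#' Evaluate predicted pairs against a gold standard
#'
#' @param predictions a [DDIPairSet-class] of predicted pairs; must be a
#'   subset of the candidate pairs
#' @param gold the gold-standard [DDIPairSet-class]
#' @param candidates the [CandidateDDISet-class] defining the universe D
#' @return an [EvaluationResult-class]
#' @export
evaluatePredictions <- function(predictions, gold, candidates) {
  stopifnot(is(predictions, "DDIPairSet"), is(gold, "DDIPairSet"),
    is(candidates, "CandidateDDISet"))
  predKeys <- pairKeys(predictions)
  candKeys <- pairKeys(candidates)
  bad <- setdiff(predKeys, candKeys)
  if (length(bad) > 0L)
    stop("predictions outside the candidate set: ",
      paste(head(gsub("\t", "-", bad), 3L), collapse = ", "))
  goldKeys <- pairKeys(gold)
  evaluationFromCounts(
    totalPredictions = length(predKeys),
    truePositives = length(intersect(predKeys, goldKeys)),
    goldInCandidates = length(intersect(goldKeys, candKeys)),
    candidateSize = length(candKeys))
}

#' Flatten an evaluation result
#'
#' @param x an `EvaluationResult`
#' @return a one-row data frame
#' @rdname evaluatePredictions
#' @export
evaluationRow <- function(x) {
  stopifnot(is(x, "EvaluationResult"))
  data.frame(total = x@totalPredictions, TP = x@truePositives,
    gold_in_candidates = x@goldInCandidates,
    candidate_size = x@candidateSize, sensitivity = x@sensitivity,
    fold_change = x@foldChange)
}

#' Sweep the slack parameter sd
#'
#' Runs inference and evaluation once per sd value, for either the
#' unweighted (`"ilp"`) or weighted (`"wilp"`) model, and returns a table
#' with one row per sd (columns sd, total, TP, sensitivity, fold_change).
#'
#' @param network a harmonized [PPINetwork-class]
#' @param composition the matching [DomainComposition-class]
#' @param gold the gold-standard [DDIPairSet-class]
#' @param model `"ilp"` (unit weights) or `"wilp"` (triangle/binning
#'   weights)
#' @param sdValues numeric vector of sd values in (0, 1]
#' @param K degree bins for the weighted model
#' @param threshold prediction threshold passed to [roundPredictions()]
#' @return a data frame, one row per sd
#' @export
sweepSD <- function(network, composition, gold, model = c("ilp", "wilp"),
                    sdValues, K = 50L, threshold = 0.5) {
  model <- match.arg(model)
  if (any(sdValues <= 0 | sdValues > 1)) stop("sd values must lie in (0, 1]")
  cand <- buildCandidatePairs(network, composition)
  wmap <- if (model == "wilp")
    computeWeights(network, composition, cand, K) else NULL
  rows <- lapply(sdValues, function(s) {
    sol <- solveLP(buildLP(cand, network, s, wmap))
    ev <- evaluatePredictions(roundPredictions(sol, threshold), gold, cand)
    cbind(data.frame(sd = s, model = model), evaluationRow(ev),
      n_fractional = nFractional(sol))
  })
  do.call(rbind, rows)
}
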