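# Cover-model linear programs and their LP-relaxation solutions.

#' Build the (weighted) slack-budgeted cover LP
#'
#' Constructs the LP relaxation of the cover model: minimize
#' `sum(w_ij d_ij)` subject to, for every observed interaction, the sum
#' of its candidate pair variables plus its slack variable being at least
#' 1, and the slack budget `sum(e_mn) <= (1 - sd) |E|`.  All variables
#' are bounded in \[0, 1\].  Unit weights give the unweighted model; with
#' `sd = 1` the budget forces every slack to 0 and the model reduces to
#' the pure parsimony-explanation cover.
#'
#' @param candidates a [CandidateDDISet-class]
#' @param network the matching harmonized [PPINetwork-class]
#' @param sd fraction of interactions that must be explained by DDIs, in
#'   \[0, 1\]; `(1 - sd) |E|` edges may be dropped via slack
#' @param weights optional [WeightMap-class] (or named numeric); unit
#'   weights when missing
#' @return an [LPProblem-class]
#' @export
buildLP <- function(candidates, network, sd = 1, weights = NULL) {
  stopifnot(is(candidates, "CandidateDDISet"), is(network, "PPINetwork"))
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0 || sd > 1)
    stop("sd must lie in [0, 1]")
  pk <- pairKeys(candidates)
  ek <- .edgeKeys(network)
  w <- if (is.null(weights)) setNames(rep(1, length(pk)), pk)
  else if (is(weights, "WeightMap")) weightValues(weights)[pk]
  else weights[pk]
  if (any(is.na(w))) stop("weights missing for some candidate pairs")
  nP <- length(pk); nE <- length(ek)
  A <- matrix(0, nE + 1L, nP + nE)
  ec <- edgeCandidates(candidates)
  for (i in seq_len(nE)) {
    A[i, match(ec[[ek[i]]], pk)] <- 1
    A[i, nP + i] <- 1
  }
  if (nE > 0L) A[nE + 1L, nP + seq_len(nE)] <- 1
  new("LPProblem", obj = c(unname(w), rep(0, nE)), mat = A,
    rhs = c(rep(1, nE), (1 - sd) * nE),
    dir = c(rep(1L, nE), -1L), pairKeys = pk, edgeKeys = ek, sd = sd)
}

#' Solve a cover LP by simplex
#'
#' Solves the LP relaxation with the package's bounded-variable primal
#' simplex.  Being a vertex method, it returns basic optimal solutions,
#' which on realistic instances are almost always integral; the number of
#' fractional variables is always reported.
#'
#' @param problem an [LPProblem-class]
#' @return a [ParsimonySolution-class]
#' @export
solveLP <- function(problem) {
  stopifnot(is(problem, "LPProblem"))
  nP <- length(problem@pairKeys); nE <- length(problem@edgeKeys)
  nv <- nP + nE
  res <- simplex_lp(problem@mat, problem@rhs, problem@dir, problem@obj,
    rep(0, nv), rep(1, nv))
  if (!identical(res$status, "optimal")) {
    return(new("ParsimonySolution",
      values = setNames(rep(NA_real_, nP), problem@pairKeys),
      slackValues = setNames(rep(NA_real_, nE), problem@edgeKeys),
      objective = NA_real_,
      solverStatus = if (identical(res$status, "infeasible")) "infeasible"
      else "error",
      nFractional = NA_integer_))
  }
  x <- res$x
  new("ParsimonySolution",
    values = setNames(x[seq_len(nP)], problem@pairKeys),
    slackValues = setNames(x[nP + seq_len(nE)], problem@edgeKeys),
    objective = res$objective, solverStatus = "optimal",
    nFractional = sum(x > 1e-6 & x < 1 - 1e-6))
}

#' @param x a `ParsimonySolution`
#' @rdname solveLP
#' @export
setMethod("solutionValues", "ParsimonySolution", function(x) x@values)

#' @rdname solveLP
#' @export
setMethod("slackValues", "ParsimonySolution", function(x) x@slackValues)

#' @rdname solveLP
#' @export
setMethod("objectiveValue", "ParsimonySolution", function(x) x@objective)

#' @rdname solveLP
#' @export
setMethod("solverStatus", "ParsimonySolution", function(x) x@solverStatus)

#' @rdname solveLP
#' @export
setMethod("nFractional", "ParsimonySolution", function(x) x@nFractional)

setMethod("show", "ParsimonySolution", function(object) {
  cat(sprintf(
    "ParsimonySolution (%s): objective %.6g, %d pair variables, %d fractional\n",
    object@solverStatus, object@objective, length(object@values),
    object@nFractional))
})

#' Threshold a solution into predicted pairs
#'
#' Pairs whose LP value is at or above the threshold are predicted.
#' Simplex optima are almost always integral, in which case any threshold
#' in (0, 1) selects the same set; fractional values are counted and
#' reported via `nFractional()`.
#'
#' @param solution an optimal [ParsimonySolution-class]
#' @param threshold inclusion threshold (default 0.5); values equal to
#'   the threshold are included
#' @return a [DDIPairSet-class]
#' @export
roundPredictions <- function(solution, threshold = 0.5) {
  stopifnot(is(solution, "ParsimonySolution"))
  if (!identical(solution@solverStatus, "optimal"))
    stop("solution is not optimal (status: ", solution@solverStatus, ")")
  keys <- names(solution@values)[solution@values >= threshold]
  DDIPairSet(.splitKeys(keys))
}

# internal: pure cover LP (no slack) on a subset of edges; variables are
# all candidate pairs, constraints only the kept edges.  Returns values
# and objective.  Pairs in no kept constraint take value 0.
.solvePE <- function(candidates, keepEdges = NULL) {
  pk <- pairKeys(candidates)
  ec <- edgeCandidates(candidates)
  if (!is.null(keepEdges)) ec <- ec[keepEdges]
  nP <- length(pk); nE <- length(ec)
  if (nE == 0L)
    return(list(values = setNames(rep(0, nP), pk), objective = 0))
  A <- matrix(0, nE, nP)
  for (i in seq_len(nE)) A[i, match(ec[[i]], pk)] <- 1
  res <- simplex_lp(A, rep(1, nE), rep(1L, nE), rep(1, nP), rep(0, nP),
    rep(1, nP))
  if (!identical(res$status, "optimal"))
    stop("PE cover LP failed: ", res$status)
  list(values = setNames(res$x, pk), objective = res$objective)
}
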