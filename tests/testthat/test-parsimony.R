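test_that("candidate pairs and their supports enumerate correctly", {
  t1 <- toy1()
  cand <- buildCandidatePairs(t1$net, t1$comp)
  expect_setequal(pairKeys(cand), c(key("A", "B"), key("A", "C")))
  expect_equal(length(supportMap(cand)[[key("A", "B")]]), 2L)
  expect_equal(length(supportMap(cand)[[key("A", "C")]]), 1L)

  homo <- buildCandidatePairs(
    PPINetwork(cbind("P5", "P6")),
    DomainComposition(list(P5 = "A", P6 = "A")))
  expect_equal(pairKeys(homo), key("A", "A"))

  cross <- buildCandidatePairs(
    PPINetwork(cbind("P7", "P8")),
    DomainComposition(list(P7 = c("A", "B"), P8 = "C")))
  expect_setequal(pairKeys(cross), c(key("A", "C"), key("B", "C")))

  expect_error(buildCandidatePairs(t1$net,
    DomainComposition(list(P1 = "A"))), "harmonize")
})

test_that("edge candidates cover both orientations of multi-domain endpoints", {
  net <- PPINetwork(cbind("P1", "P2"))
  comp <- DomainComposition(list(P1 = c("A", "B"), P2 = c("B", "C")))
  cand <- buildCandidatePairs(net, comp)
  expect_setequal(edgeCandidates(cand)[[key("P1", "P2")]],
    c(key("A", "B"), key("A", "C"), key("B", "B"), key("B", "C")))
})

test_that("triangle/binning weights reproduce the worked example", {
  t2 <- toy2()
  cand <- buildCandidatePairs(t2$net, t2$comp)
  w <- computeWeights(t2$net, t2$comp, cand, 2L)
  wv <- weightValues(w)
  expect_equal(unname(wv[key("D1", "D2")]), 0.5)
  expect_equal(unname(wv[key("D2", "D3")]), 0.5)
  expect_equal(unname(wv[key("D1", "D3")]), 1)
  expect_equal(unname(wv[key("D2", "D4")]), 1)
  expect_equal(prioritySetSize(w), 2L)
})

test_that("a pair spanning several priority interactions takes the smallest weight", {
  # two triangles through poor nodes with bin gaps 1 and 3; the shared
  # domain pair (A, B) must take 1 / (1 + 3) = 1/4
  edges <- rbind(
    c("u1", "v1"), c("u1", "q1"), c("v1", "q1"),       # triangle 1
    c("u2", "v2"), c("u2", "q2"), c("v2", "q2"),       # triangle 2
    # pad u1's and v2's degree upward with pendants
    cbind("u1", paste0("p", 1:3)),
    cbind("v2", paste0("r", 1:9)))
  net <- PPINetwork(edges)
  comp <- DomainComposition(c(
    list(u1 = "A", v1 = "B", q1 = "Z1", u2 = "A", v2 = "B", q2 = "Z2"),
    setNames(as.list(paste0("X", 1:3)), paste0("p", 1:3)),
    setNames(as.list(paste0("Y", 1:9)), paste0("r", 1:9))))
  K <- 5L
  bins <- degreeBinning(net, K)@assignment
  expect_equal(unname(bins[c("q1", "q2")]), c(1L, 1L))  # poor centers
  gap1 <- abs(bins[["u1"]] - bins[["v1"]])
  gap2 <- abs(bins[["u2"]] - bins[["v2"]])
  expect_true(gap1 != gap2)
  cand <- buildCandidatePairs(net, comp)
  w <- weightValues(computeWeights(net, comp, cand, K))
  expect_equal(unname(w[key("A", "B")]), 1 / (1 + max(gap1, gap2)))
})

test_that("K = 1 collapses every priority weight to 1", {
  t2 <- toy2()
  cand <- buildCandidatePairs(t2$net, t2$comp)
  w <- computeWeights(t2$net, t2$comp, cand, 1L)
  expect_true(all(weightValues(w) == 1))
  expect_gt(prioritySetSize(w), 0L)  # S non-empty, discounts vanish at s = t
})

test_that("LP construction counts variables, constraints and budget", {
  t1 <- toy1()
  cand <- buildCandidatePairs(t1$net, t1$comp)
  lp <- buildLP(cand, t1$net, 1)
  expect_equal(length(lp@pairKeys), 2L)
  expect_equal(length(lp@edgeKeys), 3L)
  expect_equal(nrow(lp@mat), 4L)            # 3 cover rows + budget
  expect_equal(lp@rhs[4], 0)                # sd = 1: nothing droppable
  lp2 <- buildLP(cand, t1$net, 0)
  expect_equal(lp2@rhs[4], 3)               # sd = 0: all edges droppable
  expect_error(buildLP(cand, t1$net, 1.2), "sd")
})

test_that("cover optima match exhaustive search on the worked instances", {
  t1 <- toy1()
  cand <- buildCandidatePairs(t1$net, t1$comp)
  sol <- solveLP(buildLP(cand, t1$net, 1))
  expect_equal(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 2)
  expect_equal(unname(solutionValues(sol)[key("A", "B")]), 1)
  expect_equal(unname(solutionValues(sol)[key("A", "C")]), 1)
  expect_equal(objectiveValue(sol), bruteCoverOptimum(cand, t1$net, 1))

  sol2 <- solveLP(buildLP(cand, t1$net, 2 / 3))
  expect_equal(objectiveValue(sol2), 1)
  expect_equal(objectiveValue(sol2), bruteCoverOptimum(cand, t1$net, 2 / 3))

  t2 <- toy2()
  cand2 <- buildCandidatePairs(t2$net, t2$comp)
  w2 <- computeWeights(t2$net, t2$comp, cand2, 2L)
  sol3 <- solveLP(buildLP(cand2, t2$net, 1, w2))
  expect_equal(objectiveValue(sol3), 3.0)
  expect_equal(nFractional(sol3), 0L)

  # sd = 0: dropping everything is free
  sol4 <- solveLP(buildLP(cand, t1$net, 0))
  expect_equal(objectiveValue(sol4), 0)
  expect_equal(nrow(ddiPairs(roundPredictions(sol4))), 0L)
})

test_that("the optimum is non-decreasing in sd and unit-weight WILP equals ILP", {
  for (s in 1:10) {
    inst <- randomTinyInstance(300 + s)
    if (numEdges(inst$net) == 0L) next
    cand <- buildCandidatePairs(inst$net, inst$comp)
    objs <- vapply(c(0.3, 0.6, 0.8, 1), function(sdv)
      objectiveValue(solveLP(buildLP(cand, inst$net, sdv))), numeric(1))
    expect_true(all(diff(objs) >= -1e-9))
    pk <- pairKeys(cand)
    unit <- new("WeightMap", weights = setNames(rep(1, length(pk)), pk),
      prioritySet = character(0))
    expect_equal(
      objectiveValue(solveLP(buildLP(cand, inst$net, inst$sdv, unit))),
      objectiveValue(solveLP(buildLP(cand, inst$net, inst$sdv))))
  }
})

test_that("rounded predictions with dropped edges cover every constraint", {
  for (s in 1:8) {
    inst <- randomTinyInstance(500 + s)
    if (numEdges(inst$net) == 0L) next
    cand <- buildCandidatePairs(inst$net, inst$comp)
    sol <- solveLP(buildLP(cand, inst$net, inst$sdv))
    if (nFractional(sol) > 0L) next
    pred <- pairKeys(roundPredictions(sol))
    dropped <- names(slackValues(sol))[slackValues(sol) >= 0.5]
    expect_lte(length(dropped), (1 - inst$sdv) * numEdges(inst$net) + 1)
    covered <- vapply(names(edgeCandidates(cand)), function(ek)
      ek %in% dropped || any(edgeCandidates(cand)[[ek]] %in% pred),
      logical(1))
    expect_true(all(covered))
  }
})

test_that("rounding respects the threshold boundary", {
  sol <- new("ParsimonySolution",
    values = c(a = 0, b = 1, c = 1, d = 0.5),
    slackValues = setNames(numeric(0), character(0)),
    objective = 2.5, solverStatus = "optimal", nFractional = 1L)
  # keys here are single identifiers; build via DDIPairSet on split keys
  sol@values <- setNames(sol@values,
    c(key("A", "B"), key("A", "C"), key("B", "C"), key("C", "D")))
  expect_equal(nrow(ddiPairs(roundPredictions(sol))), 3L)  # >= 0.5 included
  expect_equal(nrow(ddiPairs(roundPredictions(sol, threshold = 0.7))), 2L)
  bad <- sol; bad@solverStatus <- "error"
  expect_error(roundPredictions(bad), "not optimal")
})

test_that("witness counts require single-domain endpoints", {
  t1 <- toy1()
  w <- countWitnesses(t1$net, t1$comp)
  expect_equal(unname(w[key("A", "B")]), 2L)
  expect_equal(unname(w[key("A", "C")]), 1L)

  net <- PPINetwork(cbind("P", "Q"))
  comp <- DomainComposition(list(P = c("A", "B"), Q = "C"))
  cand <- buildCandidatePairs(net, comp)
  w2 <- countWitnesses(net, comp, cand)
  expect_equal(unname(w2[key("A", "C")]), 0L)
  expect_equal(unname(w2[key("B", "C")]), 0L)
})

test_that("LP-score at full reliability equals the deterministic PE solution", {
  t1 <- toy1()
  cand <- buildCandidatePairs(t1$net, t1$comp)
  sc <- lpScore(cand, t1$net, r = 1, nRuns = 5)
  expect_equal(unname(sc[key("A", "B")]), 1)
  expect_equal(unname(sc[key("A", "C")]), 1)
  sc2 <- lpScore(cand, t1$net, r = 1, nRuns = 50)
  expect_equal(sc, sc2)
  expect_error(lpScore(cand, t1$net, r = 0, nRuns = 5), "r must")
})

test_that("LP-score of a private-edge pair estimates the keep probability", {
  t1 <- toy1()
  cand <- buildCandidatePairs(t1$net, t1$comp)
  n <- 2000L
  sc <- lpScore(cand, t1$net, r = 0.5, nRuns = n, seed = 77)
  # (A, C) is selected iff its only edge is kept: Bernoulli(0.5) mean
  se <- sqrt(0.25 / n)
  expect_lt(abs(sc[[key("A", "C")]] - 0.5), 3 * se)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("empirical p-values are frequencies with the right extremes", {
  set.seed(31)
  ds <- generateSyntheticData(syntheticSpec(nProteins = 40L, nDomains = 12L,
    meanDegree = 3, fpRate = 0, fnRate = 0, triangleBoost = 0, seed = 31))
  net <- harmonize(ds@network, ds@composition)
  cand <- buildCandidatePairs(net, ds@composition)
  p <- empiricalPValues(cand, net, ds@composition, r = 0.8,
    nNetworks = 15L, nRuns = 3L, seed = 5)
  expect_true(all(p >= 0 & p <= 1))
  obs <- lpScore(cand, net, 0.8, 3L, seed = 5)
  # a zero-scoring pair is tied or beaten by every reference network
  if (any(obs == 0)) expect_true(all(p[names(obs)[obs == 0]] == 1))
})

test_that("pw-scores take the minimum of p-value and witness term", {
  lp <- c(x = 1, y = 1, z = 0.4)
  names(lp) <- c(key("A", "B"), key("A", "C"), key("B", "C"))
  p <- setNames(c(0.2, 0.3, 1), names(lp))
  w <- setNames(c(2L, 0L, 1L), names(lp))
  pw <- pwScore(lp, p, w, r = 0.9)
  expect_equal(unname(pw[1]), min(0.2, 0.1^2))  # 0.01
  expect_equal(unname(pw[2]), 0.3)              # (1-r)^0 = 1
  pw2 <- pwScore(lp, p, w, r = 1)
  expect_equal(unname(pw2[1]), 0)               # (1-1)^w = 0 for w >= 1
  expect_error(pwScore(lp, p[1:2], w, 0.9), "key set")
})
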