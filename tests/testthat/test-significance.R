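test_that("composition shuffles conserve counts and the domain multiset", {
  comp <- DomainComposition(list(P1 = c("A", "B"), P2 = "C", P3 = "A",
    P4 = c("C", "D", "E")))
  for (s in 1:15) {
    sh <- shuffleDomainComposition(comp, seed = s)
    expect_equal(lengths(assignments(sh)), lengths(assignments(comp)))
    expect_equal(sort(unlist(assignments(sh), use.names = FALSE)),
      sort(unlist(assignments(comp), use.names = FALSE)))
    expect_true(validObject(sh))
  }
  single <- DomainComposition(list(P1 = c("A", "B")))
  expect_equal(assignments(shuffleDomainComposition(single, seed = 1)),
    assignments(single))
  two <- DomainComposition(list(P1 = "A", P2 = "B"))
  outcomes <- unique(vapply(1:20, function(s)
    assignments(shuffleDomainComposition(two, seed = s))[["P1"]],
    character(1)))
  expect_true(all(outcomes %in% c("A", "B")))
})

test_that("edge shuffles conserve the degree sequence exactly", {
  t2 <- toy2()
  for (s in 1:10) {
    sh <- shuffleEdges(t2$net, seed = s)
    d0 <- igraph::degree(ddinfer:::.asIgraph(t2$net))
    d1 <- igraph::degree(ddinfer:::.asIgraph(sh))
    expect_equal(d1[names(d0)], d0)
  }
  k3 <- PPINetwork(cbind(c("a", "a", "b"), c("b", "c", "c")))
  expect_equal(edges(shuffleEdges(k3, seed = 2)), edges(k3))

  cyc6 <- PPINetwork(cbind(letters[1:6], letters[c(2:6, 1)]))
  for (s in 1:8) {
    sh <- shuffleEdges(cyc6, seed = s)
    expect_true(all(igraph::degree(ddinfer:::.asIgraph(sh)) == 2))
    expect_equal(numEdges(sh), 6L)
  }
})

test_that("planted-structure data give a strong parsimony signal under both shuffles", {
  # scaled-down study: 100 proteins so that the full 5-seed sweep stays fast
  for (s in defaultSpecSeeds) {
    ds <- generateSyntheticData(syntheticSpec(nProteins = 100L,
      nDomains = 40L, meanDegree = 4, seed = s))
    net <- harmonize(ds@network, ds@composition)
    for (mode in c("shuffle_compositions", "shuffle_edges")) {
      res <- parsimonyRandomizationTest(net, ds@composition, mode,
        nShuffles = 50L, seed = 1000 + s)
      expect_equal(length(nullSamples(res@null)), 50L)
      expect_gt(res@null@nullMean, res@observed)
      expect_lt(pValue(res@null), 0.01)
    }
  }
})

test_that("pure-noise data show no false parsimony signal", {
  for (s in defaultSpecSeeds) {
    net <- sampleERGraph(60, 140, seed = s)
    set.seed(s + 400)
    comp <- DomainComposition(setNames(lapply(seq_len(60), function(i)
      sample(paste0("D", 1:25), sample(1:2, 1))), proteins(net)))
    net <- harmonize(net, comp)
    for (mode in c("shuffle_edges", "shuffle_compositions")) {
      res <- parsimonyRandomizationTest(net, comp, mode,
        nShuffles = 40L, seed = 2000 + s)
      # lower-tail p: a spuriously small T0 would claim parsimony where
      # none was planted
      p <- pValue(res@null)
      expect_true(is.na(p) || p > 0.005)
    }
  }
})

test_that("gaussian p-values follow the closed form and flag degeneracy", {
  set.seed(1)
  x <- c(9, 10, 11, 10, 10.5, 9.5)
  m <- mean(x); s <- sd(x)
  expect_equal(gaussianPValue(m + 3 * s, x, "upper"),
    pnorm(3, lower.tail = FALSE))
  expect_equal(gaussianPValue(m, x, "upper"), 0.5)
  expect_equal(gaussianPValue(m, x, "lower"), 0.5)
  expect_equal(gaussianPValue(m - 2 * s, x, "lower"), pnorm(-2))
  expect_warning(p <- gaussianPValue(1, c(2, 2, 2), "upper"), "constant")
  expect_true(is.na(p))
  expect_error(gaussianPValue(1, c(2), "upper"), "2 samples")
})

test_that("random-weight nulls have the requested size and error without S", {
  ds <- generateSyntheticData(triangleSpec(21))
  net <- harmonize(ds@network, ds@composition)
  res <- randomWeightTest(net, ds@composition, ds@planted, sd = 0.5,
    K = 10L, nRuns = 5L, seed = 9)
  expect_equal(length(nullSamples(res@null)), 5L)
  expect_equal(res@statisticName, "TP")
  expect_true(res@observed >= 0)

  # a path graph has no triangles, so S is empty at any K
  path <- PPINetwork(cbind(c("a", "b", "c"), c("b", "c", "d")))
  comp <- DomainComposition(list(a = "A", b = "B", c = "C", d = "D"))
  expect_error(randomWeightTest(path, comp, DDIPairSet(cbind("A", "B")),
    sd = 0.5, K = 2L, nRuns = 5L), "no priority pairs")
})
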