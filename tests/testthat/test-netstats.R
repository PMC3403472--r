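test_that("local clustering matches hand-derived and brute-force values", {
  k3 <- PPINetwork(cbind(c("a", "a", "b"), c("b", "c", "c")))
  expect_equal(localClustering(k3, "a"), 1)

  path <- PPINetwork(cbind(c("a", "b"), c("b", "c")))
  expect_equal(localClustering(path, "b"), 0)  # one triple, no triangle
  expect_equal(localClustering(path, "a"), 0)  # degree-1 rule
  expect_error(localClustering(path, "zz"), "unknown protein")

  # K4 minus edge (b, d): vertex a sees 2 of 3 neighbor pairs connected
  k4m <- PPINetwork(cbind(c("a", "a", "a", "b", "c"),
    c("b", "c", "d", "c", "d")))
  expect_equal(localClustering(k4m, "a"), bruteLocalClustering(k4m, "a"))
  expect_equal(localClustering(k4m, "a"), 2 / 3)
})

test_that("global clustering averages local values over all vertices", {
  k4m <- PPINetwork(cbind(c("a", "a", "a", "b", "c"),
    c("b", "c", "d", "c", "d")))
  expect_equal(globalClustering(k4m), 5 / 6)

  tree <- PPINetwork(cbind(c("r", "r", "a", "a"), c("a", "b", "c", "d")))
  expect_equal(globalClustering(tree), 0)

  t2 <- toy2()
  expect_equal(globalClustering(t2$net), 0.35)

  expect_error(globalClustering(PPINetwork()), "no proteins")
})

test_that("global clustering equals exhaustive triangle counting on random graphs", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    prot <- paste0("v", seq_len(n))
    all <- t(combn(prot, 2L))
    m <- sample(0:nrow(all), 1)
    net <- PPINetwork(all[sample(nrow(all), m), , drop = FALSE],
      proteins = prot)
    expect_equal(globalClustering(net), bruteGlobalClustering(net),
      tolerance = 1e-12)
  }
})

test_that("degree binning follows the equal-width rule", {
  # degrees: h 5, a 4, b 3, c 3, d 2, e 1 -> range [1, 5]
  chain <- PPINetwork(cbind(
    c("h", "h", "h", "h", "h", "a", "a", "a", "b"),
    c("a", "b", "c", "d", "e", "b", "c", "d", "c")))
  deg <- igraph::degree(ddinfer:::.asIgraph(chain))
  b <- degreeBinning(chain, 2L)
  expect_equal(b@binEdges, c(1, 3, 5))
  expect_equal(unname(b@assignment[names(deg)[deg <= 2]]),
    rep(1L, sum(deg <= 2)))
  expect_equal(unname(b@assignment[names(deg)[deg >= 3]]),
    rep(2L, sum(deg >= 3)))

  # K = 1 puts everything in bin 1
  expect_true(all(degreeBinning(chain, 1L)@assignment == 1L))
  # regular graph: degenerate range, all bin 1 for any K
  cyc <- PPINetwork(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  expect_true(all(degreeBinning(cyc, 7L)@assignment == 1L))
  expect_error(degreeBinning(cyc, 0L), "K must be")
})

test_that("bin index is monotone non-decreasing in degree", {
  set.seed(9)
  for (i in 1:10) {
    net <- sampleERGraph(30, sample(30:120, 1), seed = i)
    deg <- igraph::degree(ddinfer:::.asIgraph(net))
    b <- degreeBinning(net, sample(2:6, 1))@assignment
    o <- order(deg)
    expect_true(all(diff(b[names(deg)[o]]) >= 0 | diff(deg[o]) > 0))
    expect_true(all(diff(b[names(deg)[o]][!duplicated(deg[o])]) >= 0))
  }
})

test_that("ER sampling has exactly m edges and forced cases are exact", {
  k4 <- sampleERGraph(4, 6, seed = 1)
  expect_equal(numEdges(k4), 6L)
  expect_equal(globalClustering(k4), 1)

  empty <- sampleERGraph(10, 0, seed = 1)
  expect_equal(numEdges(empty), 0L)
  expect_equal(globalClustering(empty), 0)
  expect_error(sampleERGraph(4, 7), "out of range")

  for (s in 1:5) expect_equal(numEdges(sampleERGraph(50, 90, seed = s)), 90L)
  # determinism
  expect_equal(edges(sampleERGraph(50, 90, seed = 3)),
    edges(sampleERGraph(50, 90, seed = 3)))
})

test_that("ER ensemble mean clustering approaches 2m/(n(n-1))", {
  n <- 1000; m <- 3000
  cc <- vapply(1:300, function(s)
    globalClustering(sampleERGraph(n, m, seed = 1000 + s)), numeric(1))
  expected <- 2 * m / (n * (n - 1))
  se <- sd(cc) / sqrt(length(cc))
  expect_lt(abs(mean(cc) - expected), 3 * se + 1e-12)
})

test_that("rewiring conserves the exact degree sequence", {
  set.seed(3)
  for (i in 1:10) {
    net <- sampleERGraph(20, sample(15:60, 1), seed = 50 + i)
    deg <- sort(igraph::degree(ddinfer:::.asIgraph(net)))
    rw <- rewirePreservingDegrees(net, seed = i)
    degNames <- igraph::degree(ddinfer:::.asIgraph(net))
    rwNames <- igraph::degree(ddinfer:::.asIgraph(rw))
    expect_equal(rwNames[names(degNames)], degNames)
    expect_equal(numEdges(rw), numEdges(net))
  }
})

test_that("rigid graphs cannot be rewired and 4-cycles stay 2-regular", {
  star <- PPINetwork(cbind(c("h", "h", "h"), c("a", "b", "c")))
  expect_equal(edges(rewirePreservingDegrees(star, seed = 1)), edges(star))

  cyc <- PPINetwork(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  for (s in 1:5) {
    rw <- rewirePreservingDegrees(cyc, seed = s)
    deg <- igraph::degree(ddinfer:::.asIgraph(rw))
    expect_true(all(deg == 2))   # one of the three 2-regular graphs on 4 labels
    expect_equal(numEdges(rw), 4L)
  }
})

test_that("clustering null distributions behave on degenerate and typical inputs", {
  k4 <- sampleERGraph(4, 6, seed = 1)
  expect_warning(nd <- clusteringNullDistribution("er", k4, nSamples = 10,
    seed = 2), "constant")
  expect_true(is.na(pValue(nd)))
  expect_equal(nd@nullMedian, 1)
  expect_equal(observedValue(nd), 1)

  # toy2's degree sequence admits a single simple graph: the hub joins
  # every vertex, forcing a-c, so the rewiring ensemble is constant too
  t2 <- toy2()
  expect_warning(nd <- clusteringNullDistribution("degree_preserving",
    t2$net, nSamples = 10, seed = 4), "constant")
  expect_equal(observedValue(nd), 0.35)
  expect_equal(nd@nullMedian, 0.35)

  ref <- sampleERGraph(12, 18, seed = 8)
  nd2 <- clusteringNullDistribution("degree_preserving", ref,
    nSamples = 20, seed = 4)
  expect_equal(length(nullSamples(nd2)), 20L)
  expect_true(all(nullSamples(nd2) >= 0 & nullSamples(nd2) <= 1))
})
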