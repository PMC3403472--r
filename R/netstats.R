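# Clustering-coefficient statistics, degree binning, and the two
# null-model graph ensembles (Erdos-Renyi G(n,m) and degree-preserving
# rewiring).

#' Watts-Strogatz local clustering coefficient
#'
#' Fraction of the pairs of neighbors of a vertex that are themselves
#' connected: triangles through the vertex divided by deg (deg - 1) / 2.
#' Vertices of degree 0 or 1 have no centered triples and are defined to
#' have coefficient 0.
#'
#' @param network a [PPINetwork-class]
#' @param protein a protein identifier in the network
#' @return a fraction in \[0, 1\]
#' @examples
#' tri <- PPINetwork(cbind(c("a", "a", "b"), c("b", "c", "c")))
#' localClustering(tri, "a")  # 1
#' @export
localClustering <- function(network, protein) {
  stopifnot(is(network, "PPINetwork"))
  if (!protein %in% proteins(network))
    stop("unknown protein: ", protein)
  g <- .asIgraph(network)
  unname(igraph::transitivity(g, type = "local", vids = protein,
    isolates = "zero"))
}

#' Watts-Strogatz global clustering coefficient
#'
#' Arithmetic mean of the local clustering coefficient over all vertices,
#' counting vertices of degree < 2 as 0.
#'
#' @param network a non-empty [PPINetwork-class]
#' @return a fraction in \[0, 1\]
#' @export
globalClustering <- function(network) {
  stopifnot(is(network, "PPINetwork"))
  if (numProteins(network) == 0L) stop("network has no proteins")
  g <- .asIgraph(network)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Partition a network's degree range into K equal-width bins
#'
#' The degree interval \[d_min, d_max\] is divided into K equal-width
#' subintervals; a node of degree d falls in bin
#' `min(K, floor((d - d_min) / width) + 1)`.  Bin 1 holds the low-degree
#' proteins ("poor nodes") and bin K the hubs.  When all degrees are equal
#' every node is assigned bin 1.
#'
#' @param network a non-empty [PPINetwork-class]
#' @param K number of subintervals, >= 1
#' @return a [DegreeBinning-class]
#' @export
degreeBinning <- function(network, K) {
  stopifnot(is(network, "PPINetwork"))
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1")
  if (numProteins(network) == 0L) stop("network has no proteins")
  deg <- igraph::degree(.asIgraph(network))
  dmin <- min(deg); dmax <- max(deg)
  if (dmax == dmin) {
    return(new("DegreeBinning", K = K,
      binEdges = seq(dmin, dmin + K, length.out = K + 1L),
      assignment = setNames(rep(1L, length(deg)), names(deg))))
  }
  width <- (dmax - dmin) / K
  bin <- pmin(K, floor((deg - dmin) / width) + 1L)
  new("DegreeBinning", K = K,
    binEdges = seq(dmin, dmax, length.out = K + 1L),
    assignment = setNames(as.integer(bin), names(deg)))
}

#' Sample an Erdos-Renyi G(n, m) graph
#'
#' A simple undirected graph with exactly `m` distinct edges drawn
#' uniformly without replacement from all n (n - 1) / 2 pairs.
#'
#' @param n node count
#' @param m edge count, 0 <= m <= n (n - 1) / 2
#' @param seed optional RNG seed for reproducibility
#' @return a [PPINetwork-class] with proteins `n1 ... n<n>`
#' @export
sampleERGraph <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 0L || m > n * (n - 1) / 2) stop("m out of range for n nodes")
  .withSeed(seed, {
    g <- igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE)
    igraph::V(g)$name <- paste0("n", seq_len(n))
    .fromIgraph(g)
  })
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes a network by repeated double-edge swaps that reject
#' self-loops and multi-edges, so the exact degree sequence is conserved.
#' `swapMultiplier * numEdges(network)` swaps are attempted.
#'
#' @param network a [PPINetwork-class] with >= 2 edges
#' @param swapMultiplier attempted swaps per edge (default 10)
#' @param seed optional RNG seed
#' @return a rewired [PPINetwork-class] with the same degree sequence
#' @export
rewirePreservingDegrees <- function(network, swapMultiplier = 10,
                                    seed = NULL) {
  stopifnot(is(network, "PPINetwork"))
  if (numEdges(network) < 2L) stop("network must have at least 2 edges")
  .withSeed(seed, {
    g <- .asIgraph(network)
    g <- igraph::rewire(g, with = igraph::keeping_degseq(loops = FALSE,
      niter = ceiling(swapMultiplier * numEdges(network))))
    .fromIgraph(g)
  })
}

#' Null distribution of the clustering coefficient
#'
#' Samples the global clustering coefficient over one of two graph
#' ensembles matched to a reference network: `"er"` draws Erdos-Renyi
#' G(n, m) graphs with the reference's node and edge counts;
#' `"degree_preserving"` rewires the reference keeping its degree
#' sequence.  Real PPI networks are expected to exceed both nulls, so the
#' upper tail is the significant one.
#'
#' @param model `"er"` or `"degree_preserving"`
#' @param reference the observed [PPINetwork-class]
#' @param nSamples ensemble size (>= 2; 500 in typical use)
#' @param seed optional RNG seed
#' @return a [NullDistribution-class]; its p-value is NA when the
#'   ensemble statistic is constant
#' @export
clusteringNullDistribution <- function(model = c("er", "degree_preserving"),
                                       reference, nSamples = 500L,
                                       seed = NULL) {
  model <- match.arg(model)
  stopifnot(is(reference, "PPINetwork"))
  nSamples <- as.integer(nSamples)
  if (nSamples < 2L) stop("nSamples must be >= 2")
  n <- numProteins(reference); m <- numEdges(reference)
  samples <- .withSeed(seed, vapply(seq_len(nSamples), function(i) {
    g <- if (model == "er") {
      gg <- igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE)
      igraph::V(gg)$name <- paste0("n", seq_len(n))
      gg
    } else {
      igraph::rewire(.asIgraph(reference),
        with = igraph::keeping_degseq(loops = FALSE, niter = 10L * m))
    }
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  }, numeric(1)))
  NullDistribution(samples, observed = globalClustering(reference),
    direction = "upper")
}
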