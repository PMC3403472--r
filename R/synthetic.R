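# Synthetic PPI + composition generator with planted DDIs.  Degree
# heterogeneity comes from skewed domain usage (promiscuous domains)
# rather than explicit preferential attachment; triangle enrichment
# closes poor-node wedges with true (explainable) edges.

#' Construct a synthetic dataset specification
#'
#' Defaults describe the desk-scale study condition used throughout the
#' package: 200 proteins, 60 domains, mean degree 5 (about 500
#' interactions), mostly single-domain proteins, 2% of domain pairs
#' planted as true DDIs, 10% spurious and 10% missing edges, and 10% of
#' closable poor-node wedges closed.
#'
#' @param nProteins,nDomains universe sizes
#' @param domainsPerProtein mean domains per protein (1 + geometric)
#' @param plantedDDIDensity fraction of all domain pairs (homodomain
#'   included) planted as true DDIs
#' @param meanDegree target mean degree of the generated network
#' @param fpRate fraction of spurious (unexplainable) edges added
#' @param fnRate fraction of true edges removed
#' @param triangleBoost probability of closing each closable poor-node
#'   wedge with its true edge
#' @param seed generator seed (required for reproducibility)
#' @return a [SyntheticSpec-class]
#' @export
syntheticSpec <- function(nProteins = 200L, nDomains = 60L,
                          domainsPerProtein = 1.5,
                          plantedDDIDensity = 0.02, meanDegree = 5,
                          fpRate = 0.1, fnRate = 0.1, triangleBoost = 0.1,
                          seed = 1L) {
  new("SyntheticSpec", nProteins = as.integer(nProteins),
    nDomains = as.integer(nDomains),
    domainsPerProtein = as.numeric(domainsPerProtein),
    plantedDDIDensity = as.numeric(plantedDDIDensity),
    meanDegree = as.numeric(meanDegree), fpRate = as.numeric(fpRate),
    fnRate = as.numeric(fnRate), triangleBoost = as.numeric(triangleBoost),
    seed = as.numeric(seed))
}

# internal: does a protein pair share at least one planted pair?
.explainable <- function(asg, plantedKeys, u, v) {
  any(outer(asg[[u]], asg[[v]], .pairKey) %in% plantedKeys)
}

#' Generate a synthetic dataset with planted DDIs
#'
#' Domains are assigned per protein with a skewed usage spectrum (a few
#' promiscuous domains, many rare ones), a planted DDI set is drawn
#' uniformly at the stated density, and edges arise from the planted
#' pairs: all protein pairs sharing a planted DDI form the potential true
#' edges, subsampled to the target mean degree.  `fnRate` of the kept
#' true edges are removed, `fpRate` spurious edges (explainable by no
#' planted pair) are added, and `triangleBoost` closes poor-node wedges
#' with further true edges, raising the clustering coefficient the way
#' real PPI networks exceed their random nulls.
#'
#' @param spec a [SyntheticSpec-class]
#' @return a [SyntheticDataset-class]
#' @export
generateSyntheticData <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  nP <- spec@nProteins; nD <- spec@nDomains
  prots <- sprintf("P%04d", seq_len(nP))
  doms <- sprintf("D%03d", seq_len(nD))
  .withSeed(spec@seed, {
    # skewed domain usage: promiscuous low-rank domains
    usage <- (seq_len(nD))^-0.8
    counts <- pmin(nD, 1L + rgeom(nP, prob = 1 / spec@domainsPerProtein))
    asg <- lapply(counts, function(k) sample(doms, k, prob = usage))
    names(asg) <- prots
    composition <- DomainComposition(asg)
    asg <- assignments(composition)
    # planted DDIs, homodomain pairs included
    idx <- which(upper.tri(matrix(0, nD, nD), diag = TRUE), arr.ind = TRUE)
    nPlanted <- round(spec@plantedDDIDensity * nrow(idx))
    if (spec@plantedDDIDensity > 0 && nPlanted == 0L)
      stop("plantedDDIDensity ", spec@plantedDDIDensity, " rounds to zero ",
        "planted pairs over ", nrow(idx), " domain pairs; increase the ",
        "density or the domain universe")
    pick <- if (nPlanted > 0L) idx[sample(nrow(idx), nPlanted), ,
      drop = FALSE] else idx[0, , drop = FALSE]
    planted <- DDIPairSet(cbind(doms[pick[, 1L]], doms[pick[, 2L]]))
    plantedKeys <- pairKeys(planted)
    # potential true edges: protein pairs sharing a planted pair
    domProts <- lapply(doms, function(d)
      prots[vapply(asg, function(a) d %in% a, logical(1))])
    names(domProts) <- doms
    base <- character(0)
    for (k in seq_along(plantedKeys)) {
      ij <- .splitKeys(plantedKeys[k])
      pu <- domProts[[ij[1L]]]; pv <- domProts[[ij[2L]]]
      if (length(pu) == 0L || length(pv) == 0L) next
      ee <- expand.grid(u = pu, v = pv, stringsAsFactors = FALSE)
      ee <- ee[ee$u != ee$v, , drop = FALSE]
      if (nrow(ee) > 0L) base <- c(base, .pairKey(ee$u, ee$v))
    }
    base <- unique(base)
    target <- round(spec@meanDegree * nP / 2)
    kept <- if (length(base) > target) sample(base, target) else base
    # false negatives
    nFN <- round(spec@fnRate * length(kept))
    if (nFN > 0L) kept <- setdiff(kept, sample(kept, nFN))
    # false positives: spurious edges explainable by no planted pair
    nFP <- round(spec@fpRate * length(kept))
    fp <- character(0)
    guard <- 0L
    while (length(fp) < nFP && guard < 50L * max(1L, nFP)) {
      guard <- guard + 1L
      uv <- sample(prots, 2L)
      k <- .pairKey(uv[1L], uv[2L])
      if (k %in% kept || k %in% fp) next
      if (.explainable(asg, plantedKeys, uv[1L], uv[2L])) next
      fp <- c(fp, k)
    }
    edgesNow <- c(kept, fp)
    # triangle enrichment: force a fraction of poor-node neighbor pairs to
    # interact through true edges.  A wedge u - p - v centered on a poor
    # protein p is closed by the edge (u, v); when no planted pair explains
    # it, the corresponding domain pair is planted, the way members of one
    # complex both interact and carry mutually recognizing domains.
    if (spec@triangleBoost > 0 && length(edgesNow) > 1L) {
      net <- PPINetwork(.splitKeys(edgesNow), proteins = prots)
      bins <- degreeBinning(net, 5L)@assignment
      poor <- names(bins)[bins == 1L]
      e <- edges(net)
      nbr <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
      wedge <- character(0)
      for (p in intersect(poor, names(nbr))) {
        np <- nbr[[p]]
        if (length(np) < 2L) next
        cmb <- combn(sort(np), 2L)
        keys <- .pairKey(cmb[1L, ], cmb[2L, ])
        wedge <- c(wedge, keys[!(keys %in% edgesNow)])
      }
      wedge <- unique(wedge)
      add <- wedge[runif(length(wedge)) < spec@triangleBoost]
      for (k in add) {
        ij <- .splitKeys(k)
        if (!.explainable(asg, plantedKeys, ij[1L], ij[2L])) {
          du <- sample(asg[[ij[1L]]], 1L)
          dv <- sample(asg[[ij[2L]]], 1L)
          plantedKeys <- c(plantedKeys, .pairKey(du, dv))
        }
      }
      planted <- DDIPairSet(.splitKeys(unique(plantedKeys)))
      plantedKeys <- pairKeys(planted)
      edgesNow <- c(edgesNow, add)
    }
    em <- .splitKeys(unique(edgesNow))
    network <- PPINetwork(em, proteins = prots)
    trueEdges <- .edgeKeys(network)
    trueEdges <- trueEdges[vapply(seq_along(trueEdges), function(q) {
      ij <- .splitKeys(trueEdges[q])
      .explainable(asg, plantedKeys, ij[1L], ij[2L])
    }, logical(1))]
    new("SyntheticDataset", network = network, composition = composition,
      planted = planted, trueEdges = trueEdges, spec = spec)
  })
}

#' Write a synthetic dataset as delimited text
#'
#' Emits `ppi.tsv` (edge list), `domains.tsv` (protein, comma-joined
#' domains), `gold.tsv` (planted pairs) in the package's input dialects,
#' plus `manifest.txt` recording every generator parameter including the
#' seed.
#'
#' @param dataset a [SyntheticDataset-class]
#' @param directory output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeDataset <- function(dataset, directory) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  pPPI <- file.path(directory, "ppi.tsv")
  pDom <- file.path(directory, "domains.tsv")
  pGold <- file.path(directory, "gold.tsv")
  pMan <- file.path(directory, "manifest.txt")
  write.table(edges(dataset@network), pPPI, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  asg <- assignments(dataset@composition)
  writeLines(paste(names(asg),
    vapply(asg, paste, character(1), collapse = ","), sep = "\t"), pDom)
  write.table(ddiPairs(dataset@planted), pGold, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  s <- dataset@spec
  writeLines(c(
    paste0("generator: ddinfer synthetic v",
      as.character(utils::packageVersion("ddinfer"))),
    paste0("seed: ", format(s@seed)),
    paste0("nProteins: ", s@nProteins),
    paste0("nDomains: ", s@nDomains),
    paste0("domainsPerProtein: ", s@domainsPerProtein),
    paste0("plantedDDIDensity: ", s@plantedDDIDensity),
    paste0("meanDegree: ", s@meanDegree),
    paste0("fpRate: ", s@fpRate),
    paste0("fnRate: ", s@fnRate),
    paste0("triangleBoost: ", s@triangleBoost),
    paste0("nEdges: ", numEdges(dataset@network)),
    paste0("nPlanted: ", nrow(ddiPairs(dataset@planted)))), pMan)
  invisible(c(pPPI, pDom, pGold, pMan))
}
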