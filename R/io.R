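# Delimited-text input/output.  All formats are plain text: an edge list
# with two identifier columns, a composition table in long ("protein
# domain") or wide ("protein dom1,dom2") form, and two-column domain-pair
# lists.  '#' starts a comment line; the default delimiter is any run of
# whitespace.

.readRows <- function(path, delimiter) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  split <- if (identical(delimiter, "") || is.null(delimiter))
    strsplit(trimws(lines), "\\s+")
  else strsplit(lines, delimiter, fixed = TRUE)
  list(fields = split, lineno = lineno)
}

#' Read a PPI edge list
#'
#' Reads a two-column delimited text file of interacting protein pairs.
#' Rows are canonicalized (the order of the two identifiers is
#' irrelevant), duplicate rows are merged, and self-interactions are
#' dropped; both events are counted in the attached [LoadReport-class].
#' Extra columns are ignored; lines starting with `#` are comments.
#'
#' @param path file path
#' @param delimiter field separator; `""` (default) splits on any
#'   whitespace
#' @return a [PPINetwork-class]; `loadReport(x)` holds the counts
#' @examples
#' f <- tempfile()
#' writeLines(c("P1 P2", "P2 P1", "P3 P3"), f)
#' net <- readPPIEdgeList(f)
#' loadReport(net)
#' @export
readPPIEdgeList <- function(path, delimiter = "") {
  rows <- .readRows(path, delimiter)
  nf <- lengths(rows$fields)
  if (any(nf < 2L))
    stop("parse error in ", path, " line ", rows$lineno[which(nf < 2L)[1L]],
      ": expected at least 2 fields")
  n <- length(rows$fields)
  if (n == 0L) {
    return(PPINetwork(metadata = list(loadReport = new("LoadReport"))))
  }
  a <- vapply(rows$fields, `[[`, character(1), 1L)
  b <- vapply(rows$fields, `[[`, character(1), 2L)
  selfs <- sum(a == b)
  key <- .pairKey(a[a != b], b[a != b])
  dups <- sum(duplicated(key))
  net <- PPINetwork(cbind(a, b))
  net@metadata$loadReport <- new("LoadReport", rowsRead = n,
    selfLoopsDropped = as.integer(selfs),
    duplicateEdgesMerged = as.integer(dups))
  net
}

#' Read a protein domain composition table
#'
#' Accepts either long format (one `protein domain` row per assignment) or
#' wide format (`protein dom1,dom2,...`), auto-detected per row by the
#' presence of commas in the second field.  Repeated protein rows are
#' unioned and domain sets deduplicated.
#'
#' @inheritParams readPPIEdgeList
#' @return a [DomainComposition-class]
#' @examples
#' f <- tempfile()
#' writeLines(c("P1 A", "P1 B", "P2 A,C"), f)
#' assignments(readDomainComposition(f))
#' @export
readDomainComposition <- function(path, delimiter = "") {
  rows <- .readRows(path, delimiter)
  nf <- lengths(rows$fields)
  if (any(nf < 2L))
    stop("parse error in ", path, " line ", rows$lineno[which(nf < 2L)[1L]],
      ": expected 'protein domain' or 'protein dom1,dom2,...'")
  if (length(rows$fields) == 0L) return(DomainComposition())
  prot <- vapply(rows$fields, `[[`, character(1), 1L)
  doms <- lapply(rows$fields, function(f)
    unlist(strsplit(f[-1L], ",", fixed = TRUE)))
  DomainComposition(split(unlist(doms),
    rep(prot, lengths(doms))))
}

#' Read a set of domain pairs
#'
#' Two columns of domain identifiers per row; pairs are canonicalized and
#' deduplicated.  Homodomain pairs (A, A) are retained: a domain may
#' interact with another copy of itself.
#'
#' @inheritParams readPPIEdgeList
#' @return a [DDIPairSet-class]
#' @export
readDDIPairs <- function(path, delimiter = "") {
  rows <- .readRows(path, delimiter)
  nf <- lengths(rows$fields)
  if (any(nf < 2L))
    stop("parse error in ", path, " line ", rows$lineno[which(nf < 2L)[1L]],
      ": expected 2 fields")
  if (length(rows$fields) == 0L) return(DDIPairSet())
  DDIPairSet(cbind(vapply(rows$fields, `[[`, character(1), 1L),
    vapply(rows$fields, `[[`, character(1), 2L)))
}

#' Restrict a network to proteins with a domain composition
#'
#' Returns the induced subnetwork on proteins present in the composition
#' table; edges with at least one unannotated endpoint are removed and
#' counted.  Inference requires harmonized inputs: every edge endpoint
#' must have at least one domain.
#'
#' @param network a [PPINetwork-class]
#' @param composition a [DomainComposition-class]
#' @return a [PPINetwork-class] whose `loadReport` counts the proteins
#'   removed
#' @export
harmonize <- function(network, composition) {
  stopifnot(is(network, "PPINetwork"), is(composition, "DomainComposition"))
  annotated <- names(assignments(composition))
  keep <- proteins(network) %in% annotated
  nDropped <- sum(!keep)
  e <- edges(network)
  e <- e[e[, 1L] %in% annotated & e[, 2L] %in% annotated, , drop = FALSE]
  out <- PPINetwork(e, proteins = proteins(network)[keep])
  if (numProteins(out) == 0L)
    warning("no protein of the network has a domain composition")
  out@metadata$loadReport <- new("LoadReport",
    proteinsWithoutComposition = as.integer(nDropped))
  out
}

#' Tabulate and write predictions
#'
#' `predictionTable()` assembles one row per candidate pair with its LP
#' value, weight, support count and predicted flag, ordered by descending
#' LP value then lexicographic pair.  `writePredictions()` writes the
#' table as a six-column TSV with a header.
#'
#' @param solution a [ParsimonySolution-class]
#' @param candidates the [CandidateDDISet-class] the model was built from
#' @param weights optional [WeightMap-class]; unit weights when missing
#' @param threshold LP value at or above which a pair is predicted
#' @return `predictionTable()`: a data frame with columns `domain_i`,
#'   `domain_j`, `lp_value`, `weight`, `n_supporting_edges`, `predicted`
#' @export
predictionTable <- function(solution, candidates, weights = NULL,
                            threshold = 0.5) {
  stopifnot(is(solution, "ParsimonySolution"),
    is(candidates, "CandidateDDISet"))
  keys <- pairKeys(candidates)
  vals <- solution@values[keys]
  w <- if (is.null(weights)) rep(1, length(keys)) else
    weightValues(weights)[keys]
  ids <- .splitKeys(keys)
  df <- data.frame(domain_i = ids[, 1L], domain_j = ids[, 2L],
    lp_value = unname(vals), weight = unname(w),
    n_supporting_edges = unname(lengths(supportMap(candidates)[keys])),
    predicted = unname(vals >= threshold), stringsAsFactors = FALSE)
  df[order(-df$lp_value, df$domain_i, df$domain_j), , drop = FALSE]
}

#' @param predictions a data frame from `predictionTable()`
#' @param path output file path
#' @rdname predictionTable
#' @export
writePredictions <- function(predictions, path) {
  stopifnot(is.data.frame(predictions))
  ok <- tryCatch({
    write.table(predictions, path, sep = "\t", quote = FALSE,
      row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write predictions to ", path, ": ",
    conditionMessage(e)))
  invisible(ok)
}

#' Read back a predictions table
#'
#' @param path a TSV written by [writePredictions()]
#' @return the predictions data frame
#' @rdname predictionTable
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
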