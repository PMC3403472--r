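# shared internal helpers

# canonical key for an unordered identifier pair; identifiers must not
# contain the tab character (enforced by the delimited readers)
.pairKey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\t")

.splitKeys <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L))
  }
  matrix(unlist(strsplit(keys, "\t", fixed = TRUE)), ncol = 2L, byrow = TRUE)
}

# canonicalize an n x 2 identifier matrix so the lexicographically smaller
# identifier comes first in each row
.canonicalRows <- function(m) {
  if (nrow(m) == 0L) return(m)
  cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream;
# seed = NULL uses (and advances) the current stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

.msg <- function(...) message("[ddinfer] ", ...)
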