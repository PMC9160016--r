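# Internal helpers shared across the package.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. With seed = NULL the current stream is
# used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation so we can save the state
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Canonical string key for an unordered pair / triple of 0-based labels.
pair_key <- function(u, v) {
  lo <- pmin(u, v); hi <- pmax(u, v)
  paste(lo, hi, sep = "-")
}

triple_key <- function(u, v, w) {
  if (!length(u)) return(character(0))
  lo <- pmin(u, v, w); hi <- pmax(u, v, w)
  mid <- as.integer(u) + as.integer(v) + as.integer(w) - lo - hi
  paste(lo, mid, hi, sep = "-")
}

# Normalise an edge/triangle matrix: integer storage, sorted within rows,
# sorted across rows, duplicates dropped. Accepts a 0-row matrix.
canonical_rows <- function(x, ncol) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(0), ncol = ncol))
  }
  x <- matrix(as.integer(x), ncol = ncol)
  if (nrow(x) > 0L) {
    x <- t(apply(x, 1L, sort.int, method = "radix"))
    if (ncol == 1L) x <- t(x)
    o <- do.call(order, lapply(seq_len(ncol), function(j) x[, j]))
    x <- x[o, , drop = FALSE]
    x <- x[!duplicated(x), , drop = FALSE]
  }
  dimnames(x) <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
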