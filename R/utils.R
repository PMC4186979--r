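# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Lower-triangle (i > j) vector of a symmetric matrix, column-major order --
# the n(n-1)/2 unordered distance pairs.
lower_tri <- function(m) m[lower.tri(m)]

# Pairwise Euclidean distance matrix of the rows of x.
euclid_full <- function(x) as.matrix(stats::dist(as.matrix(x), method = "euclidean"))

stop_if_not_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric", call. = FALSE)
  invisible(m)
}

# Union-find over n elements for grouping duplicate compounds.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

`%||%` <- function(a, b) if (is.null(a)) b else a
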