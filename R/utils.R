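# Internal helpers shared across modules.

# Indices of the strict upper triangle, as a 2-column matrix (i < j).
.upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Run `expr` with a local RNG state. `seed = NULL` leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation (keeps values in [1, 2^31 - 2]).
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69621 + 1013 * k) %% 2147483646 + 1)
}

# Truncated normal sampler by inverse-CDF; robust for wide bounds.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Union-find over nodes 1..n for an edge list; returns a component root per
# node (path-halving). Used for suprathreshold component extraction and the
# per-permutation max-extent statistic, where it is far cheaper than building
# a full graph object thousands of times.
.uf_roots <- function(ei, ej, n) {
  parent <- seq_len(n)
  for (k in seq_along(ei)) {
    a <- ei[k]
    while (parent[a] != a) {
      parent[a] <- parent[parent[a]]
      a <- parent[a]
    }
    b <- ej[k]
    while (parent[b] != b) {
      parent[b] <- parent[parent[b]]
      b <- parent[b]
    }
    if (a != b) parent[a] <- b
  }
  for (v in seq_len(n)) {
    r <- v
    while (parent[r] != r) r <- parent[r]
    parent[v] <- r
  }
  parent
}

# Largest component extent (edge count) of an edge list; 0 for empty input.
.max_component_extent <- function(ei, ej, n) {
  if (length(ei) == 0L) return(0L)
  roots <- .uf_roots(ei, ej, n)
  max(tabulate(roots[ei], nbins = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
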