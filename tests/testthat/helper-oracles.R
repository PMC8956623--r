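# Independent brute-force oracles used to validate the metric
# implementations, plus small fixture builders. Everything here is written
# as literally as possible (scalar loops, no shared code with the package
# internals).

# Random symmetric FA-like weight matrix; edges present with prob `density`.
rand_weights <- function(n, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) {
        w[i, j] <- w[j, i] <- runif(1, 0.2, 0.7)
      }
    }
  }
  w
}

oracle_degree_strength <- function(w) {
  n <- nrow(w)
  k <- integer(n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && w[i, j] > 0) {
        k[i] <- k[i] + 1L
        s[i] <- s[i] + w[i, j]
      }
    }
  }
  list(degree = k, strength = s, total = sum(s))
}

# Triangle intensity by exhaustive ordered-triple enumeration (halved), and
# the clustering coefficient from it.
oracle_clustering <- function(w) {
  n <- nrow(w)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i != j && j != k && k != i &&
            w[i, j] > 0 && w[j, k] > 0 && w[k, i] > 0) {
          t_i[i] <- t_i[i] + (w[i, j] * w[j, k] * w[k, i])^(1 / 3)
        }
      }
    }
  }
  t_i <- t_i / 2
  deg <- oracle_degree_strength(w)$degree
  c_i <- ifelse(deg >= 2, 2 * t_i / (deg * (deg - 1)), 0)
  list(triangle_intensity = t_i, nodal = c_i, global = mean(c_i))
}

# All-pairs shortest paths, scalar Floyd-Warshall on reciprocal lengths.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Single-source Dijkstra with a linear scan (lengths = 1/w).
oracle_dijkstra <- function(w, src) {
  n <- nrow(w)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- NA
    best <- Inf
    for (v in seq_len(n)) {
      if (!done[v] && dist[v] < best) {
        best <- dist[v]
        u <- v
      }
    }
    if (is.na(u)) break
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (w[u, v] > 0 && dist[u] + 1 / w[u, v] < dist[v])
        dist[v] <- dist[u] + 1 / w[u, v]
    }
  }
  dist
}

# Literal neighbour-subgraph local efficiency: enumerate neighbour pairs,
# shortest paths inside the induced neighbour subgraph by Dijkstra.
oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    acc <- 0
    for (a in seq_len(k)) {
      dist_a <- oracle_dijkstra(sub, a)
      for (b in seq_len(k)) {
        if (a != b && is.finite(dist_a[b]) && dist_a[b] > 0) {
          acc <- acc + (w[i, nb[a]] * w[i, nb[b]] / dist_a[b])^(1 / 3)
        }
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# Tiny path graph 1-2-3 with both weights 0.5; used by several hand-computed
# examples.
path3_net <- function(w12 = 0.5, w23 = 0.5) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w12
  w[2, 3] <- w[3, 2] <- w23
  weighted_network(w)
}

complete_net <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  weighted_network(w)
}

# Cohort of identical-support control subjects where edge presence per
# subject follows fixed prevalence classes; subject k has a class-c edge iff
# k <= count_c. The class layout makes the FP/FN curves cross so that the
# minimax group threshold is exactly 0.66 on a 0.01 grid:
#   24 edges present in all 20 subjects, 10 edges in 14/20, 2 edges in
#   13/20, 30 edges in 1/20.
crossing_fixture_cohort <- function() {
  n_sub <- 20
  n_nodes <- 12
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  counts <- c(rep(20, 24), rep(14, 10), rep(13, 2), rep(1, 30))
  stopifnot(nrow(pairs) >= length(counts))
  networks <- lapply(seq_len(n_sub), function(k) {
    w <- matrix(0, n_nodes, n_nodes)
    on_edges <- which(counts >= k)
    for (e in on_edges) {
      i <- pairs[e, 1]
      j <- pairs[e, 2]
      w[i, j] <- w[j, i] <- 0.5
    }
    weighted_network(w)
  })
  subjects <- data.frame(subject_id = sprintf("HC%02d", seq_len(n_sub)),
                         group = "HC", age = 30 + seq_len(n_sub),
                         sex = rep(c(0, 1), length.out = n_sub))
  cohort_dataset(subjects, networks, control = "HC")
}

# Small three-group null cohort helper used across statistical tests.
tiny_spec <- function(n_nodes = 12, n = 15, noise_sd = 0.05) {
  cohort_spec(n_per_group = c(HC = n, MS = n, NMOSD = n),
              n_nodes = n_nodes, density = 0.6, noise_sd = noise_sd)
}

cohort_covs <- function(cohort) {
  cbind(age = cohort$subjects$age, sex = cohort$subjects$sex)
}

total_strengths <- function(cohort) {
  vapply(cohort$networks, function(n) sum(n$weights), numeric(1))
}
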