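# Weighted graph-theory measures on FA-weighted structural networks.
#
# Conventions used throughout:
#   * an edge exists iff w_ij > 0; the binary adjacency is never stored;
#   * path length between adjacent nodes is the reciprocal of the edge
#     weight (strong connections are short), shortest paths by Dijkstra;
#   * node pairs with no connecting path are ignored when averaging path
#     lengths and contribute efficiency 0.

#' Nodal degree and strength
#'
#' Degree `K_i` counts the neighbours of node i (entries with `w_ij > 0`);
#' nodal strength `S_i` is the row sum of weights. Total strength, the global
#' version, is the sum of nodal strengths over all nodes, so each undirected
#' edge contributes twice — the row-sum convention.
#'
#' @param net A [weighted_network()].
#' @return List with `degree` (integer vector), `strength` (numeric vector)
#'   and `total_strength` (scalar).
#' @export
degree_strength <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  k <- as.integer(rowSums(w > 0))
  s <- rowSums(w)
  list(degree = setNames(k, net$labels),
       strength = setNames(s, net$labels),
       total_strength = sum(s))
}

#' Weighted clustering coefficient
#'
#' Triangle intensity of node i is `t_i = (1/2) * sum_{j,k} (w_ij w_jk
#' w_ki)^(1/3)` (each triangle counted once); the nodal clustering
#' coefficient is `C_i = 2 t_i / (K_i (K_i - 1))`, with `C_i = 0` by
#' convention when `K_i < 2`. The global coefficient averages `C_i` over all
#' nodes, zeros included.
#'
#' @param net A [weighted_network()].
#' @return List with `triangle_intensity`, `nodal` (C_i) and `global`.
#' @export
clustering_coef <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w13 <- net$weights^(1 / 3)
  t_i <- diag(w13 %*% w13 %*% w13) / 2
  k <- rowSums(net$weights > 0)
  c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  list(triangle_intensity = setNames(t_i, net$labels),
       nodal = setNames(c_i, net$labels),
       global = mean(c_i))
}

#' Shortest-path length matrix
#'
#' Dijkstra shortest paths with edge length `1/w_ij`. Entries for
#' disconnected pairs are `Inf`; the diagonal is 0.
#'
#' @param net A [weighted_network()].
#' @return Numeric n x n matrix of path lengths.
#' @export
shortest_paths_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wt)) 1 / wt else numeric(0),
                         algorithm = "dijkstra")
  dimnames(d) <- list(net$labels, net$labels)
  d
}

# Floyd-Warshall on a direct-length matrix (Inf where no edge, zero
# diagonal); used for the small neighbour subgraphs of local efficiency,
# where it is cheaper than repeated graph construction.
.fw_distances <- function(len) {
  d <- len
  for (k in seq_len(nrow(len)))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

.reciprocal_lengths <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest-path lengths: `L = sum(d_ij) / D`
#' with `D` the number of finite ordered pairs. Disconnected pairs are
#' ignored; a network with no finite pair at all is an error.
#'
#' @param d Distance matrix from [shortest_paths_matrix()].
#' @return Scalar path length.
#' @export
characteristic_path_length <- function(d) {
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0)
    stop("network is fully disconnected: no finite path length to average",
         call. = FALSE)
  mean(fin)
}

#' Global efficiency
#'
#' `E_glob = (1/N) sum_i sum_{j != i} d_ij^{-1} / (N - 1)`, with
#' `d_ij^{-1} = 0` for disconnected pairs.
#'
#' @param d Distance matrix from [shortest_paths_matrix()].
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(d) {
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Regional efficiency
#'
#' Per-node mean of inverse shortest-path lengths to every other node:
#' `E_reg(i) = (1/(N-1)) sum_{j != i} 1/d_ij`; disconnected pairs contribute
#' zero, so an isolated node has efficiency 0.
#'
#' @param d Distance matrix from [shortest_paths_matrix()].
#' @return Numeric vector, one value per node.
#' @export
regional_efficiency <- function(d) {
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Local efficiency
#'
#' For node i with degree `K_i >= 2`, the local subgraph is induced by the
#' neighbours of i (i itself excluded). The nodal value sums, over ordered
#' neighbour pairs (j, k), `(w_ij w_ik [d_jk]^(-1))^(1/3)` with `d_jk` the
#' shortest-path length *within the neighbour subgraph* (reciprocal-weight
#' lengths; disconnected pairs contribute 0), divided by `K_i (K_i - 1)`.
#' Nodes with fewer than two neighbours score 0. The global value is the mean
#' over all nodes, zeros included.
#'
#' @param net A [weighted_network()].
#' @return List with `nodal` (numeric vector) and `global` (scalar).
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  n <- net$n
  e_loc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    dsub <- .fw_distances(.reciprocal_lengths(w[nb, nb, drop = FALSE]))
    inv <- 1 / dsub
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    wi <- w[i, nb]
    terms <- (outer(wi, wi) * inv)^(1 / 3)
    e_loc[i] <- sum(terms) / (k * (k - 1))
  }
  list(nodal = setNames(e_loc, net$labels), global = mean(e_loc))
}

#' Compute the full metric set for one network
#'
#' One pass over a subject's network producing every nodal measure (degree,
#' strength, triangle intensity, clustering, local efficiency, regional
#' efficiency) and the five global measures used in group comparisons: total
#' strength, clustering coefficient, characteristic path length, local
#' efficiency and global efficiency.
#'
#' @param net A [weighted_network()].
#' @return Object of class `metric_set`: list with `nodal` (data frame, one
#'   row per region) and `global` (named numeric vector of length 5).
#' @export
network_metrics <- function(net) {
  ds <- degree_strength(net)
  cc <- clustering_coef(net)
  d <- shortest_paths_matrix(net)
  le <- local_efficiency(net)
  nodal <- data.frame(region = net$labels,
                      degree = as.integer(ds$degree),
                      strength = as.numeric(ds$strength),
                      triangle_intensity = as.numeric(cc$triangle_intensity),
                      clustering = as.numeric(cc$nodal),
                      local_efficiency = as.numeric(le$nodal),
                      regional_efficiency = as.numeric(regional_efficiency(d)),
                      stringsAsFactors = FALSE)
  global <- c(total_strength = ds$total_strength,
              clustering_coef = cc$global,
              char_path_length = characteristic_path_length(d),
              local_efficiency = le$global,
              global_efficiency = global_efficiency(d))
  structure(list(nodal = nodal, global = global), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set> ", nrow(x$nodal), " regions\n", sep = "")
  print(round(x$global, 4))
  invisible(x)
}

#' Per-subject metrics for a whole cohort
#'
#' @param cohort A [cohort_dataset()].
#' @param nodal Logical; also return per-node measure matrices.
#' @return List with `global` (data frame: subject_id, group, one column per
#'   global measure) and, if `nodal`, `nodal` (list of subjects x regions
#'   matrices, one per nodal measure).
#' @export
cohort_metrics <- function(cohort, nodal = TRUE) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  ms <- lapply(cohort$networks, network_metrics)
  glob <- do.call(rbind, lapply(ms, function(m) m$global))
  global <- data.frame(subject_id = cohort$subjects$subject_id,
                       group = cohort$subjects$group,
                       glob, stringsAsFactors = FALSE, row.names = NULL)
  out <- list(global = global)
  if (nodal) {
    meas <- c("degree", "strength", "clustering", "local_efficiency",
              "regional_efficiency")
    out$nodal <- lapply(setNames(meas, meas), function(v) {
      m <- do.call(rbind, lapply(ms, function(x) x$nodal[[v]]))
      dimnames(m) <- list(cohort$subjects$subject_id, cohort$labels)
      m
    })
  }
  out
}
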