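# Network-based statistics: mass-univariate edge-wise ANCOVA, cluster
# forming on the edge F statistics, and family-wise error control on
# component extent (edge count) via a permutation null of the maximum
# extent. The same Freedman-Lane permutation stream drives every edge within
# a permutation, so one permutation yields one full edge-stat matrix and one
# max-extent draw.

#' Edge-wise partial F statistics
#'
#' Computes, for every retained edge, the partial F of the group factor on
#' that edge's weights across subjects, controlling for age and sex —
#' identical to calling [partial_f()] on each edge's weight vector.
#'
#' @param cohort A screened [cohort_dataset()] (same mask applied to every
#'   subject).
#' @param mask Optional logical matrix (or [screen_edges()] result)
#'   restricting the tested edges; defaults to edges present in at least one
#'   subject.
#' @return Symmetric n x n matrix of F values; untested edges are `NA`.
#' @export
edgewise_stats <- function(cohort, mask = NULL) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  prep <- .edge_test_prep(cohort, mask)
  f <- .fl_fstat(prep$Y, prep$setup)
  stats <- matrix(NA_real_, cohort$n_nodes, cohort$n_nodes,
                  dimnames = list(cohort$labels, cohort$labels))
  stats[prep$pairs] <- f
  stats[prep$pairs[, c(2, 1), drop = FALSE]] <- f
  stats
}

# Shared preparation for edge-wise testing: retained pairs, subject x edge
# weight matrix, and the Freedman-Lane setup.
.edge_test_prep <- function(cohort, mask = NULL) {
  if (inherits(mask, "edge_screening")) mask <- mask$mask
  pairs <- .upper_pairs(cohort$n_nodes)
  if (is.null(mask)) {
    present <- matrix(FALSE, cohort$n_nodes, cohort$n_nodes)
    for (net in cohort$networks) present <- present | (net$weights > 0)
    keep <- present[pairs]
  } else {
    if (!is.matrix(mask) || nrow(mask) != cohort$n_nodes)
      stop("mask dimensions do not match the cohort", call. = FALSE)
    keep <- mask[pairs]
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no edges to test after masking", call. = FALSE)
  Y <- .edge_matrix(cohort, pairs)
  setup <- .fl_setup(.group_term(cohort$subjects$group),
                     .cohort_covariates(cohort))
  list(pairs = pairs, Y = Y, setup = setup)
}

#' Connected components of the suprathreshold graph
#'
#' Keeps edges whose statistic meets the cluster-forming threshold
#' (`F >= threshold`, inclusive) and extracts connected components of the
#' resulting graph. Component size is its *extent* — the number of edges.
#'
#' @param stats Symmetric matrix of edge statistics (`NA` = untested edge).
#' @param threshold Positive cluster-forming threshold.
#' @return List of components sorted by decreasing extent (ties by smallest
#'   node index); each is a list with `nodes` (indices), `node_labels`,
#'   `edges` (2-column index matrix, rows ordered), `extent`.
#' @export
suprathreshold_components <- function(stats, threshold) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  n <- nrow(stats)
  pairs <- .upper_pairs(n)
  vals <- stats[pairs]
  keep <- !is.na(vals) & vals >= threshold
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(list())
  roots <- .uf_roots(pairs[, 1], pairs[, 2], n)
  edge_root <- roots[pairs[, 1]]
  comps <- lapply(unique(edge_root), function(r) {
    e <- pairs[edge_root == r, , drop = FALSE]
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    nodes <- sort(unique(as.vector(e)))
    list(nodes = nodes,
         node_labels = if (!is.null(rownames(stats))) rownames(stats)[nodes],
         edges = e, extent = nrow(e))
  })
  ord <- order(-vapply(comps, `[[`, numeric(1), "extent"),
               vapply(comps, function(c) c$nodes[1], numeric(1)))
  comps[ord]
}

#' Network-based statistic test
#'
#' Full NBS inference on a screened cohort: edge-wise partial F for the
#' group factor (age/sex-adjusted), cluster forming at
#' `config$nbs_threshold`, and a permutation null distribution of the
#' maximum component extent (Freedman-Lane residual permutation, one shared
#' permutation per edge-stat matrix). Each observed component gets
#' `p_fwer = (1 + #\{max extent* >= extent\}) / (1 + n_perm)`. Components
#' significant at `config$alpha` receive post-hoc per-edge pairwise tables
#' via [posthoc_edges()].
#'
#' @param cohort A screened [cohort_dataset()].
#' @param config An [analysis_config()]; `n_permutations` must be >= 100.
#' @param mask Optional mask (or [screen_edges()] result) of tested edges.
#' @param posthoc Logical; run post-hoc edge tests on significant components
#'   (default `TRUE`).
#' @return Object of class `nbs_result`: `components` (each with `p_fwer`),
#'   `stats` (edge F matrix), `threshold`, `n_perm`, `null_max_extent`
#'   (numeric vector), `posthoc` (list of per-component tables), and
#'   `statistic = "partial_F"` metadata.
#' @export
nbs_test <- function(cohort, config = analysis_config(), mask = NULL,
                     posthoc = TRUE) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (config$n_permutations < 100)
    stop("NBS requires at least 100 permutations", call. = FALSE)
  prep <- .edge_test_prep(cohort, mask)
  s <- prep$setup
  f_obs <- .fl_fstat(prep$Y, s)
  stats <- matrix(NA_real_, cohort$n_nodes, cohort$n_nodes,
                  dimnames = list(cohort$labels, cohort$labels))
  stats[prep$pairs] <- f_obs
  stats[prep$pairs[, c(2, 1), drop = FALSE]] <- f_obs
  comps <- suprathreshold_components(stats, config$nbs_threshold)

  R0 <- prep$Y - s$Q0 %*% crossprod(s$Q0, prep$Y)
  r0ss <- colSums(R0^2)
  n_perm <- config$n_permutations
  null_max <- numeric(n_perm)
  .with_seed(.child_seed(config$seed, 7), {
    for (b in seq_len(n_perm)) {
      rp <- R0[sample.int(s$n), , drop = FALSE]
      rss0p <- pmax(r0ss - colSums(crossprod(s$Q0, rp)^2), 0)
      rssfp <- pmax(r0ss - colSums(crossprod(s$Qf, rp)^2), 0)
      fp <- .f_from_rss(rss0p, rssfp, s, r0ss)
      supra <- which(fp >= config$nbs_threshold)
      null_max[b] <- .max_component_extent(prep$pairs[supra, 1],
                                           prep$pairs[supra, 2],
                                           cohort$n_nodes)
    }
  })
  for (k in seq_along(comps))
    comps[[k]]$p_fwer <- (1 + sum(null_max >= comps[[k]]$extent)) /
      (1 + n_perm)

  ph <- list()
  if (posthoc && length(comps)) {
    for (k in seq_along(comps)) {
      if (comps[[k]]$p_fwer <= config$alpha)
        ph[[length(ph) + 1]] <- posthoc_edges(cohort, comps[[k]]$edges,
                                              config)
    }
  }
  structure(list(components = comps, stats = stats,
                 threshold = config$nbs_threshold, n_perm = n_perm,
                 null_max_extent = null_max, posthoc = ph,
                 alpha = config$alpha, statistic = "partial_F"),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> cluster-forming threshold F >= ", x$threshold, ", ",
      x$n_perm, " permutations\n", sep = "")
  if (length(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      c <- x$components[[k]]
      cat(sprintf("  component %d: extent %d edges, %d nodes, p_fwer = %.4g%s\n",
                  k, c$extent, length(c$nodes), c$p_fwer,
                  if (c$p_fwer <= x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.nbs_result <- function(object, ...) {
  sig <- vapply(object$components, function(c) c$p_fwer <= object$alpha,
                logical(1))
  data.frame(component = seq_along(object$components),
             extent = vapply(object$components, `[[`, numeric(1), "extent"),
             n_nodes = vapply(object$components,
                              function(c) length(c$nodes), integer(1)),
             p_fwer = vapply(object$components, `[[`, numeric(1), "p_fwer"),
             significant = sig)
}

#' Post-hoc pairwise tests on a component's edges
#'
#' For each edge: three pairwise permutation ANCOVAs (age/sex-adjusted) with
#' FDR correction across the three comparisons, plus `A < B` direction
#' labels taken from covariate-adjusted group means.
#'
#' @param cohort A [cohort_dataset()].
#' @param edges 2-column matrix of node indices (one row per edge), as in a
#'   component from [suprathreshold_components()].
#' @param config An [analysis_config()].
#' @return Data frame, one row per edge: `edge` label plus, per pair,
#'   `p_<pair>`, `p_fdr_<pair>`, `dir_<pair>` columns.
#' @export
posthoc_edges <- function(cohort, edges, config = analysis_config()) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) stop("empty edge set", call. = FALSE)
  Y <- .edge_matrix(cohort, edges)
  groups <- cohort$subjects$group
  covs <- .cohort_covariates(cohort)
  lev <- levels(droplevels(groups))
  pair_keys <- combn(lev, 2, FUN = function(p) .pair_key(p[1], p[2]))
  out <- data.frame(edge = paste0(cohort$labels[edges[, 1]], "-",
                                  cohort$labels[edges[, 2]]),
                    stringsAsFactors = FALSE)
  for (k in pair_keys) {
    out[[paste0("p_", k)]] <- NA_real_
    out[[paste0("p_fdr_", k)]] <- NA_real_
    out[[paste0("dir_", k)]] <- NA_character_
  }
  for (e in seq_len(nrow(edges))) {
    pw <- .pairwise_tests(Y[, e], groups, covs, config$n_permutations,
                          .child_seed(config$seed, 5000 + e),
                          config$fdr_method)
    for (k in seq_along(pair_keys)) {
      out[[paste0("p_", pair_keys[k])]][e] <- pw$p[k]
      out[[paste0("p_fdr_", pair_keys[k])]][e] <- pw$p_fdr[k]
      out[[paste0("dir_", pair_keys[k])]][e] <- pw$direction[k]
    }
  }
  out
}

#' Count significant rows in a post-hoc table
#'
#' Number of rows whose (adjusted) p-value in the named column falls below
#' `alpha`.
#'
#' @param table Data frame (e.g. from [posthoc_edges()] or
#'   [reference_posthoc_table()]).
#' @param column Name of the p-value column to count.
#' @param alpha Significance level (default 0.05).
#' @return Integer count.
#' @export
count_significant <- function(table, column, alpha = 0.05) {
  if (!column %in% names(table))
    stop("unknown column: ", column, call. = FALSE)
  sum(table[[column]] < alpha, na.rm = TRUE)
}
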