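# Prevalence-based edge screening.
#
# Tractography-derived matrices contain spurious (false-positive) and missed
# (false-negative) connections. Screening keeps only edges whose prevalence
# across control subjects reaches a group threshold chosen to balance the
# two error counts, then applies that control-derived mask to every group.

#' Per-edge prevalence in the control group
#'
#' The prevalence of an edge is the fraction of control subjects in which it
#' exists (weight strictly positive). If every control subject has the
#' connection its prevalence is one.
#'
#' @param cohort A [cohort_dataset()].
#' @return Symmetric n x n matrix of fractions in \[0, 1\] (zero diagonal).
#' @export
prevalence_rates <- function(cohort) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  ctrl <- which(cohort$subjects$group == cohort$control)
  if (length(ctrl) == 0) stop("cohort has no control subjects", call. = FALSE)
  acc <- matrix(0, cohort$n_nodes, cohort$n_nodes)
  for (k in ctrl) acc <- acc + (cohort$networks[[k]]$weights > 0)
  prev <- acc / length(ctrl)
  dimnames(prev) <- list(cohort$labels, cohort$labels)
  prev
}

#' False-positive / false-negative counts across candidate thresholds
#'
#' For each candidate group threshold `tau`, edges with prevalence `>= tau`
#' form the existing set. Counting over control subjects and unordered node
#' pairs: a false negative is an existing edge absent (weight 0) in a
#' subject; a false positive is a non-existing edge present in a subject.
#' Raising `tau` shrinks the existing set, so FN counts are non-increasing
#' and FP counts non-decreasing in `tau`.
#'
#' @param cohort A [cohort_dataset()].
#' @param prevalence Matrix from [prevalence_rates()].
#' @param grid Numeric vector of candidate thresholds in \[0, 1\].
#' @return Data frame with columns `threshold`, `fp`, `fn`.
#' @export
fp_fn_curves <- function(cohort, prevalence, grid) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  if (any(grid < 0 | grid > 1))
    stop("grid thresholds must lie in [0, 1]", call. = FALSE)
  ctrl <- which(cohort$subjects$group == cohort$control)
  pairs <- .upper_pairs(cohort$n_nodes)
  prev <- prevalence[pairs]
  pres <- .edge_matrix(cohort, pairs) > 0
  pres <- pres[ctrl, , drop = FALSE]
  n_present <- colSums(pres)                 # subjects with the edge
  n_absent <- length(ctrl) - n_present
  fp <- fn <- numeric(length(grid))
  # prevalences are ratios k/n and grid values multiples of the step; the
  # >= comparison gets a small slack so representation noise cannot flip it
  for (g in seq_along(grid)) {
    existing <- prev >= grid[g] - 1e-9
    fn[g] <- sum(n_absent[existing])
    fp[g] <- sum(n_present[!existing])
  }
  data.frame(threshold = grid, fp = fp, fn = fn)
}

#' Optimal group threshold
#'
#' The balancing point minimising both error counts, operationalised as the
#' grid threshold minimising `max(FP, FN)`; ties break toward the smaller
#' threshold, which retains more edges.
#'
#' @param curves Data frame from [fp_fn_curves()] (columns `threshold`,
#'   `fp`, `fn`).
#' @return The chosen threshold.
#' @export
optimal_threshold <- function(curves) {
  stopifnot(all(c("threshold", "fp", "fn") %in% names(curves)))
  worst <- pmax(curves$fp, curves$fn)
  ord <- order(curves$threshold)
  worst <- worst[ord]
  thr <- curves$threshold[ord]
  thr[which.min(worst)]
}

#' Screen a cohort's edges
#'
#' Full screening stage: control-group prevalence, FP/FN curves over a
#' regular threshold grid, minimax threshold choice, and the resulting edge
#' mask (`prevalence >= chosen threshold`).
#'
#' @param cohort A [cohort_dataset()].
#' @param config An [analysis_config()]; `screening_grid_step` sets the grid.
#' @return Object of class `edge_screening`: list with `prevalence`,
#'   `curves`, `chosen_threshold`, `mask` (logical matrix) and
#'   `n_edges_retained`.
#' @export
screen_edges <- function(cohort, config = analysis_config()) {
  prev <- prevalence_rates(cohort)
  grid <- seq(0, 1, by = config$screening_grid_step)
  curves <- fp_fn_curves(cohort, prev, grid)
  thr <- optimal_threshold(curves)
  mask <- prev >= thr - 1e-9
  diag(mask) <- FALSE
  structure(list(prevalence = prev, curves = curves, chosen_threshold = thr,
                 mask = mask,
                 n_edges_retained = sum(mask[upper.tri(mask)])),
            class = "edge_screening")
}

#' @export
print.edge_screening <- function(x, ...) {
  n <- nrow(x$mask)
  cat("<edge_screening> chosen group threshold: ", x$chosen_threshold, "\n",
      sep = "")
  cat("  edges retained: ", x$n_edges_retained, " of ", n * (n - 1) / 2,
      "\n", sep = "")
  invisible(x)
}

#' Apply an edge mask to every subject
#'
#' Sets weights outside the mask to zero in every subject's network — the
#' control-derived mask is applied to all groups. The input cohort is not
#' modified; masking is idempotent.
#'
#' @param cohort A [cohort_dataset()].
#' @param mask Logical symmetric n x n matrix (or an `edge_screening`
#'   object, whose mask is used).
#' @return A new [cohort_dataset()] with masked networks.
#' @export
apply_mask <- function(cohort, mask) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (inherits(mask, "edge_screening")) mask <- mask$mask
  if (!is.matrix(mask) || nrow(mask) != cohort$n_nodes ||
      ncol(mask) != cohort$n_nodes)
    stop("mask dimensions do not match the cohort (", cohort$n_nodes,
         " nodes)", call. = FALSE)
  if (!isTRUE(all(mask == t(mask))))
    stop("mask must be symmetric", call. = FALSE)
  out <- cohort
  keep <- mask & !diag(TRUE, cohort$n_nodes)
  out$networks <- lapply(cohort$networks, function(net) {
    net$weights[!keep] <- 0
    net
  })
  out
}
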