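#' Assemble a cohort of subjects with networks and covariates
#'
#' A `connstat_cohort` bundles one [weighted_network()] per subject with the
#' subject table used by every statistical stage: group membership (one
#' designated control group plus one or more disease groups), age in years,
#' binary sex code, and optional clinical scores (e.g. EDSS, disease duration
#' in years) which may be missing — they are typically undefined for healthy
#' controls and are excluded pairwise downstream.
#'
#' @param subjects Data frame with columns `subject_id`, `group`, `age`,
#'   `sex`, plus any clinical columns.
#' @param networks List of [weighted_network()] objects, one per subject row,
#'   all sharing the same region labels and node count.
#' @param control Name of the control group level (default `"HC"`).
#' @param clinical Character vector naming the clinical columns of `subjects`
#'   (default: every column beyond the four required ones).
#' @return An object of class `connstat_cohort`.
#' @export
cohort_dataset <- function(subjects, networks, control = "HC",
                           clinical = NULL) {
  req <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols))
    stop("subject table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (is.null(clinical)) clinical <- setdiff(names(subjects), req)
  n_sub <- nrow(subjects)
  if (length(networks) != n_sub)
    stop("number of networks (", length(networks),
         ") does not match subject rows (", n_sub, ")", call. = FALSE)
  if (!all(vapply(networks, inherits, logical(1), "weighted_network")))
    stop("all elements of `networks` must be weighted_network objects",
         call. = FALSE)
  n0 <- networks[[1]]$n
  lab0 <- networks[[1]]$labels
  for (k in seq_along(networks)) {
    if (networks[[k]]$n != n0)
      stop("inconsistent dimensions: subject '", subjects$subject_id[k],
           "' has ", networks[[k]]$n, " nodes, expected ", n0, call. = FALSE)
    if (!identical(networks[[k]]$labels, lab0))
      stop("subject '", subjects$subject_id[k],
           "' has a different region-label order", call. = FALSE)
  }
  if (!control %in% subjects$group)
    stop("control group '", control, "' not present in the cohort",
         call. = FALSE)
  if (any(!is.finite(subjects$age)) || any(subjects$age <= 0))
    stop("ages must be finite and > 0", call. = FALSE)
  if (!all(subjects$sex %in% c(0, 1)))
    stop("`sex` must be coded 0/1", call. = FALSE)
  for (cl in clinical) {
    v <- subjects[[cl]]
    if (!is.numeric(v))
      stop("clinical column '", cl, "' must be numeric", call. = FALSE)
    if (any(!is.na(v) & !is.finite(v)))
      stop("clinical column '", cl, "' has non-finite values", call. = FALSE)
  }
  grp <- factor(subjects$group,
                levels = c(control, sort(setdiff(unique(subjects$group),
                                                 control))))
  subjects$group <- grp
  names(networks) <- subjects$subject_id
  structure(list(subjects = subjects, networks = networks,
                 labels = lab0, n_nodes = n0, control = control,
                 clinical = clinical),
            class = "connstat_cohort")
}

#' @export
print.connstat_cohort <- function(x, ...) {
  cat("<connstat_cohort> ", nrow(x$subjects), " subjects, ", x$n_nodes,
      " nodes\n", sep = "")
  tab <- table(x$subjects$group)
  cat("  groups: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      " (control: ", x$control, ")\n", sep = "")
  if (length(x$clinical))
    cat("  clinical: ", paste(x$clinical, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A [cohort_dataset()].
#' @return Integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

# Stack one edge per column over subjects: returns n_subjects x n_edges
# matrix for the upper-triangle pairs `pairs` (2-column index matrix).
.edge_matrix <- function(cohort, pairs) {
  flat <- pairs[, 1] + (pairs[, 2] - 1) * cohort$n_nodes
  t(vapply(cohort$networks, function(net) net$weights[flat],
           numeric(length(flat))))
}
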