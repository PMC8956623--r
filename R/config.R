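#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults mirror common
#' practice for three-group structural connectome comparisons: a
#' cluster-forming threshold of 3.0 on the edge-wise F statistic, 10,000
#' permutations, alpha 0.05, Benjamini-Hochberg FDR, and a screening grid in
#' steps of 0.01.
#'
#' @param nbs_threshold Positive cluster-forming threshold applied to
#'   edge-wise F statistics (inclusive, `F >= threshold`).
#' @param n_permutations Number of permutations (>= 100).
#' @param alpha Significance level in (0, 1).
#' @param fdr_method Multiple-comparison method for [fdr_adjust()]; only
#'   `"BH"` is currently implemented (Bonferroni available for debugging).
#' @param seed Integer seed driving every random stage, or `NULL`.
#' @param screening_grid_step Step of the group-threshold grid in (0, 1).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(nbs_threshold = 3.0, n_permutations = 10000,
                            alpha = 0.05, fdr_method = "BH", seed = NULL,
                            screening_grid_step = 0.01) {
  if (!is.numeric(nbs_threshold) || nbs_threshold <= 0)
    stop("`nbs_threshold` must be > 0", call. = FALSE)
  if (!is.numeric(n_permutations) || n_permutations < 100)
    stop("`n_permutations` must be >= 100", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  if (!fdr_method %in% c("BH", "bonferroni"))
    stop("unknown `fdr_method`: ", fdr_method, call. = FALSE)
  if (!is.numeric(screening_grid_step) || screening_grid_step <= 0 ||
      screening_grid_step >= 1)
    stop("`screening_grid_step` must lie in (0, 1)", call. = FALSE)
  structure(list(nbs_threshold = nbs_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, fdr_method = fdr_method,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 screening_grid_step = screening_grid_step),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields mirror the arguments of [analysis_config()]; absent fields keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  nbs_threshold: ", x$nbs_threshold, " | n_permutations: ",
      x$n_permutations, " | alpha: ", x$alpha, "\n", sep = "")
  cat("  fdr_method: ", x$fdr_method, " | seed: ",
      if (is.null(x$seed)) "none" else x$seed, " | screening grid step: ",
      x$screening_grid_step, "\n", sep = "")
  invisible(x)
}
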