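# Associations between network measures and clinical scores, fitted within
# one disease group at a time with age and sex controlled:
#   clinical = b0 + b1 * measure + b2 * age + b3 * sex + error.
# The clinical variable is the response, matching the stated model; b1 is
# the coefficient of interest, reported unstandardized.

#' Fit the clinical-association model for one group
#'
#' Ordinary least squares of a clinical score on a network measure plus age
#' and sex, within a single group. Subjects with a missing clinical value
#' are dropped (pairwise exclusion). The significance of the measure
#' coefficient `b1` is the analytic partial F by default; a Freedman-Lane
#' permutation p-value on the measure term is available.
#'
#' @param cohort A [cohort_dataset()].
#' @param measure Numeric vector of the network measure, one value per
#'   cohort subject (in subject order).
#' @param clinical Name of the clinical column of the cohort.
#' @param group Group level to fit within.
#' @param measure_name Label stored with the fit.
#' @param permutation Logical; add a permutation p-value for `b1`.
#' @param n_perm,seed Permutation settings when `permutation = TRUE`.
#' @param min_n Minimum complete cases required (default 5).
#' @return Object of class `glm_fit`: `coefficients` (b0..b3), `p_beta1`,
#'   `conf_int_beta1` (95%), `n_used`, `clinical_name`, `measure_name`,
#'   `group`, and `p_beta1_perm` when requested.
#' @export
fit_association <- function(cohort, measure, clinical, group,
                            measure_name = deparse(substitute(measure)),
                            permutation = FALSE, n_perm = 10000,
                            seed = NULL, min_n = 5) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (!clinical %in% names(cohort$subjects))
    stop("unknown clinical variable: ", clinical, call. = FALSE)
  if (length(measure) != nrow(cohort$subjects))
    stop("`measure` must have one value per subject", call. = FALSE)
  idx <- which(cohort$subjects$group == group &
                 !is.na(cohort$subjects[[clinical]]))
  if (length(idx) < min_n)
    stop("fewer than ", min_n, " complete cases in group '", group,
         "' for '", clinical, "'", call. = FALSE)
  d <- data.frame(clin = cohort$subjects[[clinical]][idx],
                  measure = measure[idx],
                  age = cohort$subjects$age[idx],
                  sex = cohort$subjects$sex[idx])
  X <- cbind(1, d$measure, d$age, d$sex)
  if (qr(X)$rank < ncol(X))
    stop("collinear/degenerate design for '", clinical, "' ~ '",
         measure_name, "' in group '", group, "'", call. = FALSE)
  fit <- lm(clin ~ measure + age + sex, data = d)
  co <- coef(fit)
  sm <- summary(fit)$coefficients
  out <- list(coefficients = setNames(as.numeric(co),
                                      c("beta0", "beta1", "beta2", "beta3")),
              p_beta1 = sm["measure", "Pr(>|t|)"],
              conf_int_beta1 = as.numeric(confint(fit, "measure",
                                                  level = 0.95)),
              n_used = length(idx), clinical_name = clinical,
              measure_name = measure_name, group = group)
  if (permutation) {
    res <- .perm_ancova_mat(cbind(d$clin), cbind(d$measure),
                            cbind(d$age, d$sex), n_perm, seed)
    out$p_beta1_perm <- as.numeric(res$p_perm)
  }
  structure(out, class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> ", x$clinical_name, " ~ ", x$measure_name,
      " + age + sex  [group ", x$group, ", n = ", x$n_used, "]\n", sep = "")
  cat("  beta1 = ", sprintf("%.4g", x$coefficients["beta1"]),
      " (95% CI ", sprintf("%.4g", x$conf_int_beta1[1]), " to ",
      sprintf("%.4g", x$conf_int_beta1[2]), "), p = ",
      sprintf("%.4g", x$p_beta1), "\n", sep = "")
  if (!is.null(x$p_beta1_perm))
    cat("  permutation p = ", sprintf("%.4g", x$p_beta1_perm), "\n",
        sep = "")
  invisible(x)
}

#' Association table between global measures and clinical scores
#'
#' One [fit_association()] row per (disease group, global measure, clinical
#' variable). Groups with no usable clinical values (e.g. healthy controls)
#' are skipped with a message; rows whose design is degenerate carry the
#' error text in `note` with `NA` estimates.
#'
#' @param cohort A [cohort_dataset()].
#' @param metrics Optional precomputed [cohort_metrics()] result.
#' @param clinical Clinical variables to fit (default: all in the cohort).
#' @param measures Global measures to fit (default: all five).
#' @param groups Groups to fit within (default: all non-control).
#' @param ... Passed to [fit_association()] (e.g. `permutation = TRUE`).
#' @return Data frame with columns `group`, `clinical`, `measure`, `beta1`,
#'   `p_beta1`, `n_used`, `note`.
#' @export
association_table <- function(cohort, metrics = NULL,
                              clinical = cohort$clinical,
                              measures = c("total_strength",
                                           "clustering_coef",
                                           "char_path_length",
                                           "local_efficiency",
                                           "global_efficiency"),
                              groups = NULL, ...) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (is.null(metrics)) metrics <- cohort_metrics(cohort, nodal = FALSE)
  if (is.null(groups))
    groups <- setdiff(levels(cohort$subjects$group), cohort$control)
  rows <- list()
  for (g in groups) {
    for (cl in clinical) {
      usable <- sum(cohort$subjects$group == g &
                      !is.na(cohort$subjects[[cl]]))
      if (usable == 0) {
        message("group '", g, "' has no values for '", cl, "'; skipped")
        next
      }
      for (m in measures) {
        row <- data.frame(group = g, clinical = cl, measure = m,
                          beta1 = NA_real_, p_beta1 = NA_real_,
                          n_used = NA_integer_, note = "",
                          stringsAsFactors = FALSE)
        fit <- tryCatch(
          fit_association(cohort, metrics$global[[m]], cl, g,
                          measure_name = m, ...),
          error = function(e) conditionMessage(e))
        if (inherits(fit, "glm_fit")) {
          row$beta1 <- fit$coefficients["beta1"]
          row$p_beta1 <- fit$p_beta1
          row$n_used <- fit$n_used
        } else row$note <- fit
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
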