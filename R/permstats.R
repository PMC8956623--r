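# Permutation-based ANCOVA with nuisance covariates (Freedman-Lane scheme),
# FDR correction, and the global/nodal group-comparison tables.
#
# The tested term (group dummies) is assessed by its partial F given the
# covariates:
#   F = ((RSS_reduced - RSS_full) / df1) / (RSS_full / df2),
# reduced model = intercept + covariates, full model adds the term.
# Permutation null: residuals of the reduced fit are permuted and added back
# to the reduced fit (Freedman-Lane), which respects the covariates; with no
# covariates this reduces to plain label permutation.

.fl_setup <- function(term, nuisance = NULL) {
  term <- as.matrix(term)
  n <- nrow(term)
  X0 <- matrix(1, n, 1)
  if (!is.null(nuisance)) X0 <- cbind(X0, as.matrix(nuisance))
  q0 <- qr(X0)
  if (q0$rank < ncol(X0))
    stop("singular design: collinear nuisance covariates", call. = FALSE)
  Xf <- cbind(X0, term)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf))
    stop("singular design: tested term collinear with covariates",
         call. = FALSE)
  df1 <- qf$rank - q0$rank
  df2 <- n - qf$rank
  if (df2 < 1)
    stop("no residual degrees of freedom (n too small for the design)",
         call. = FALSE)
  list(Q0 = qr.Q(q0)[, seq_len(q0$rank), drop = FALSE],
       Qf = qr.Q(qf)[, seq_len(qf$rank), drop = FALSE],
       df1 = df1, df2 = df2, n = n)
}

# Partial F from reduced/full RSS vectors; `scale` sets the tolerance that
# separates an exactly-fit response (F := 0 or Inf) from rounding noise.
.f_from_rss <- function(rss0, rssf, s, scale) {
  tol <- 1e-11 * pmax(scale, .Machine$double.eps)
  num <- pmax(rss0 - rssf, 0) / s$df1
  den <- rssf / s$df2
  f <- num / den
  degen <- rssf <= tol
  f[degen & num <= tol] <- 0
  f[degen & num > tol] <- Inf
  f
}

.fl_fstat <- function(Y, s) {
  yss <- colSums(Y^2)
  rss0 <- pmax(yss - colSums(crossprod(s$Q0, Y)^2), 0)
  rssf <- pmax(yss - colSums(crossprod(s$Qf, Y)^2), 0)
  .f_from_rss(rss0, rssf, s, yss)
}

# Permutation ANCOVA over the columns of Y (n subjects x m responses) with a
# shared permutation stream across columns. Returns observed F, permutation
# p-values and the degrees of freedom.
.perm_ancova_mat <- function(Y, term, nuisance, n_perm, seed) {
  s <- .fl_setup(term, nuisance)
  Y <- as.matrix(Y)
  f_obs <- .fl_fstat(Y, s)
  R0 <- Y - s$Q0 %*% crossprod(s$Q0, Y)
  r0ss <- colSums(R0^2)
  m <- ncol(Y)
  count <- numeric(m)
  .with_seed(seed, {
    if (m == 1L) {
      # vectorize across permutations for a single response
      perms <- vapply(seq_len(n_perm), function(b) R0[sample.int(s$n), 1],
                      numeric(s$n))
      rss0p <- pmax(r0ss - colSums(crossprod(s$Q0, perms)^2), 0)
      rssfp <- pmax(r0ss - colSums(crossprod(s$Qf, perms)^2), 0)
      fp <- .f_from_rss(rss0p, rssfp, s, rep(r0ss, n_perm))
      count <- sum(fp >= f_obs)
    } else {
      for (b in seq_len(n_perm)) {
        rp <- R0[sample.int(s$n), , drop = FALSE]
        rss0p <- pmax(r0ss - colSums(crossprod(s$Q0, rp)^2), 0)
        rssfp <- pmax(r0ss - colSums(crossprod(s$Qf, rp)^2), 0)
        count <- count + (.f_from_rss(rss0p, rssfp, s, r0ss) >= f_obs)
      }
    }
  })
  list(statistic = f_obs, p_perm = (1 + count) / (1 + n_perm),
       df = c(s$df1, s$df2))
}

.group_term <- function(groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs at least 2 subjects",
                         call. = FALSE)
  model.matrix(~groups)[, -1, drop = FALSE]
}

#' Partial F statistic for a group effect adjusted for covariates
#'
#' @param y Numeric response vector (no missing values).
#' @param groups Group labels (coerced to factor), >= 2 groups of >= 2.
#' @param covariates Optional numeric matrix/data frame of nuisance
#'   covariates (e.g. age and sex), or `NULL`.
#' @return List with `statistic` (the partial F) and `df` (numerator,
#'   denominator degrees of freedom).
#' @export
partial_f <- function(y, groups, covariates = NULL) {
  if (anyNA(y)) stop("`y` contains missing values", call. = FALSE)
  s <- .fl_setup(.group_term(groups), covariates)
  list(statistic = as.numeric(.fl_fstat(cbind(y), s)),
       df = c(s$df1, s$df2))
}

#' Permutation-based ANCOVA for a group effect
#'
#' Tests the group factor on `y` while controlling for covariates, using
#' Freedman-Lane residual permutation: residuals of the covariate-only model
#' are permuted, added back to its fitted values, and the partial F is
#' recomputed. The p-value uses the add-one convention
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`, so the smallest attainable value
#' is `1/(n_perm + 1)`.
#'
#' @inheritParams partial_f
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Object of class `ancova_result`: `statistic`, `df`, `p_perm`,
#'   `group_adjusted_means`, `n_perm`.
#' @export
permutation_ancova <- function(y, groups, covariates = NULL,
                               n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (anyNA(y)) stop("`y` contains missing values", call. = FALSE)
  term <- .group_term(groups)
  res <- .perm_ancova_mat(cbind(y), term, covariates, n_perm, seed)
  structure(list(statistic = as.numeric(res$statistic), df = res$df,
                 p_perm = as.numeric(res$p_perm),
                 group_adjusted_means = adjusted_group_means(y, groups,
                                                             covariates),
                 n_perm = as.integer(n_perm)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("<ancova_result> F(", x$df[1], ", ", x$df[2], ") = ",
      sprintf("%.4g", x$statistic), ", permutation p = ",
      sprintf("%.4g", x$p_perm), " (", x$n_perm, " permutations)\n", sep = "")
  cat("  adjusted means: ",
      paste(sprintf("%s = %.4g", names(x$group_adjusted_means),
                    x$group_adjusted_means), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted group means
#'
#' Group means predicted from the full linear model at the overall covariate
#' means; used for the `A < B` direction labels of comparison tables.
#'
#' @inheritParams partial_f
#' @return Named numeric vector, one adjusted mean per group level.
#' @export
adjusted_group_means <- function(y, groups, covariates = NULL) {
  groups <- droplevels(factor(groups))
  term <- model.matrix(~groups)[, -1, drop = FALSE]
  X <- cbind(1, if (is.null(covariates)) NULL else as.matrix(covariates),
             term)
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  q <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  covmean <- if (q) colMeans(as.matrix(covariates)) else numeric(0)
  lev <- levels(groups)
  out <- vapply(seq_along(lev), function(g) {
    dummy <- as.numeric(seq_len(nlevels(groups) - 1) == (g - 1))
    sum(c(1, covmean, dummy) * beta)
  }, numeric(1))
  setNames(out, lev)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, input order preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"` (debugging aid).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, method = "BH") {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

.pair_key <- function(a, b) paste0(a, "_vs_", b)

# All pairwise permutation ANCOVAs for one response over group levels.
# Returns a data.frame: pair, p (raw), p_fdr, direction.
.pairwise_tests <- function(y, groups, covariates, n_perm, seed,
                            fdr_method = "BH") {
  groups <- droplevels(factor(groups))
  lev <- levels(groups)
  prs <- combn(lev, 2, simplify = FALSE)
  raw <- numeric(length(prs))
  dir <- character(length(prs))
  for (k in seq_along(prs)) {
    keep <- groups %in% prs[[k]]
    cv <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[keep, , drop = FALSE]
    res <- .perm_ancova_mat(cbind(y[keep]), .group_term(groups[keep]), cv,
                            n_perm, .child_seed(seed, k))
    raw[k] <- res$p_perm
    am <- adjusted_group_means(y[keep], groups[keep], cv)
    dir[k] <- if (am[prs[[k]][1]] <= am[prs[[k]][2]])
      paste(prs[[k]][1], "<", prs[[k]][2]) else
        paste(prs[[k]][2], "<", prs[[k]][1])
  }
  data.frame(pair = vapply(prs, function(p) .pair_key(p[1], p[2]),
                           character(1)),
             p = raw, p_fdr = fdr_adjust(raw, fdr_method), direction = dir,
             stringsAsFactors = FALSE)
}

.cohort_covariates <- function(cohort) {
  cbind(age = cohort$subjects$age, sex = cohort$subjects$sex)
}

#' Compare global network measures between groups
#'
#' For each of the five global measures (total strength, clustering
#' coefficient, characteristic path length, local efficiency, global
#' efficiency): an omnibus permutation ANCOVA across all groups controlling
#' for age and sex, followed by the three pairwise post-hoc permutation
#' ANCOVAs with FDR correction across the pairs. Per-group raw mean and SD
#' are reported alongside.
#'
#' @param cohort A [cohort_dataset()].
#' @param config An [analysis_config()].
#' @param metrics Optional precomputed result of [cohort_metrics()].
#' @return Data frame of class `comparison_table`, one row per (measure,
#'   pair): columns `measure`, `pair`, per-group `mean_*`/`sd_*`,
#'   `p_omnibus`, `p_pair`, `p_pair_fdr`, `direction`.
#' @export
compare_global <- function(cohort, config = analysis_config(),
                           metrics = NULL) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (is.null(metrics)) metrics <- cohort_metrics(cohort, nodal = FALSE)
  gl <- metrics$global
  groups <- cohort$subjects$group
  covs <- .cohort_covariates(cohort)
  meas <- c("total_strength", "clustering_coef", "char_path_length",
            "local_efficiency", "global_efficiency")
  out <- list()
  for (i in seq_along(meas)) {
    y <- gl[[meas[i]]]
    om <- .perm_ancova_mat(cbind(y), .group_term(groups), covs,
                           config$n_permutations,
                           .child_seed(config$seed, 100 + i))
    pw <- .pairwise_tests(y, groups, covs, config$n_permutations,
                          .child_seed(config$seed, 200 + i),
                          config$fdr_method)
    stats_by_group <- tapply(y, groups, function(v) c(mean(v), sd(v)))
    row <- data.frame(measure = meas[i], pair = pw$pair,
                      p_omnibus = as.numeric(om$p_perm),
                      p_pair = pw$p, p_pair_fdr = pw$p_fdr,
                      direction = pw$direction, stringsAsFactors = FALSE)
    for (g in levels(groups)) {
      row[[paste0("mean_", g)]] <- stats_by_group[[g]][1]
      row[[paste0("sd_", g)]] <- stats_by_group[[g]][2]
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("comparison_table", class(res))
  res
}

#' Compare nodal network measures between groups
#'
#' For each nodal measure: omnibus permutation ANCOVA at every node
#' (age/sex-adjusted, shared permutation stream across nodes), FDR
#' correction across the nodes, and — for nodes surviving FDR at
#' `config$alpha` — the three pairwise post-hoc tests with FDR across the
#' pairs. Pairwise columns are `NA` for non-surviving nodes.
#'
#' @param cohort A [cohort_dataset()].
#' @param config An [analysis_config()].
#' @param measures Character vector of nodal measures (subset of `degree`,
#'   `strength`, `clustering`, `local_efficiency`, `regional_efficiency`).
#' @param metrics Optional precomputed result of [cohort_metrics()].
#' @return Data frame of class `comparison_table`: one row per (measure,
#'   region) with `p_omnibus`, `p_fdr`, `significant`, and per-pair
#'   `p_<pair>`, `p_fdr_<pair>`, `dir_<pair>` columns.
#' @export
compare_nodal <- function(cohort, config = analysis_config(),
                          measures = c("strength", "clustering",
                                       "local_efficiency",
                                       "regional_efficiency"),
                          metrics = NULL) {
  stopifnot(inherits(cohort, "connstat_cohort"))
  if (is.null(metrics)) metrics <- cohort_metrics(cohort, nodal = TRUE)
  groups <- cohort$subjects$group
  covs <- .cohort_covariates(cohort)
  lev <- levels(droplevels(groups))
  prs <- combn(lev, 2, simplify = FALSE)
  pair_keys <- vapply(prs, function(p) .pair_key(p[1], p[2]), character(1))
  out <- list()
  for (i in seq_along(measures)) {
    Y <- metrics$nodal[[measures[i]]]
    if (is.null(Y)) stop("unknown nodal measure: ", measures[i],
                         call. = FALSE)
    om <- .perm_ancova_mat(Y, .group_term(groups), covs,
                           config$n_permutations,
                           .child_seed(config$seed, 300 + i))
    p_fdr <- fdr_adjust(as.numeric(om$p_perm), config$fdr_method)
    sig <- p_fdr <= config$alpha
    tab <- data.frame(measure = measures[i], region = colnames(Y),
                      p_omnibus = as.numeric(om$p_perm), p_fdr = p_fdr,
                      significant = sig, stringsAsFactors = FALSE)
    for (k in pair_keys) {
      tab[[paste0("p_", k)]] <- NA_real_
      tab[[paste0("p_fdr_", k)]] <- NA_real_
      tab[[paste0("dir_", k)]] <- NA_character_
    }
    for (j in which(sig)) {
      pw <- .pairwise_tests(Y[, j], groups, covs, config$n_permutations,
                            .child_seed(config$seed, 1000 * i + j),
                            config$fdr_method)
      for (k in seq_along(pair_keys)) {
        tab[[paste0("p_", pair_keys[k])]][j] <- pw$p[k]
        tab[[paste0("p_fdr_", pair_keys[k])]][j] <- pw$p_fdr[k]
        tab[[paste0("dir_", pair_keys[k])]][j] <- pw$direction[k]
      }
    }
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  class(res) <- c("comparison_table", class(res))
  res
}
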