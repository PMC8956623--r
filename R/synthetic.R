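# Synthetic three-group cohorts of FA-weighted connectomes with known
# ground truth: a shared template topology, per-group global attenuation, a
# planted (connected) disrupted subnetwork, optional covariate effects on
# edge weights, and clinical scores generated from a linear model on a true
# global network measure. Defaults emulate an MS / NMOSD / healthy-control
# DTI cohort: weights in the FA-plausible range [0.2, 0.7], ~60% density,
# modest additive subject noise, and group age distributions with an older
# NMOSD group.

#' Cohort generation parameters
#'
#' @param n_per_group Named integer vector of subjects per group; the first
#'   name is taken as the control group.
#' @param n_nodes Number of regions.
#' @param density Target edge density of the template in (0, 1].
#' @param weight_mean,weight_sd,weight_min,weight_max Truncated-normal
#'   parameters for template edge weights (FA-like, default range
#'   \[0.2, 0.7\]).
#' @param noise_sd SD of additive Gaussian subject noise per edge (clipped
#'   at 0).
#' @param age_mean,age_sd Named numeric vectors (per group) for Gaussian age
#'   sampling, truncated below at `age_min`.
#' @param age_min Minimum age in years.
#' @param sex_prob Probability of sex code 1 (female) per subject.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HC = 15, MS = 15, NMOSD = 15),
                        n_nodes = 90, density = 0.6,
                        weight_mean = 0.45, weight_sd = 0.1,
                        weight_min = 0.2, weight_max = 0.7,
                        noise_sd = 0.04,
                        age_mean = c(HC = 35, MS = 35, NMOSD = 44),
                        age_sd = c(HC = 9, MS = 9, NMOSD = 12),
                        age_min = 18, sex_prob = 0.7) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("`n_per_group` must be a named vector of group sizes", call. = FALSE)
  if (any(n_per_group < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]", call. = FALSE)
  if (density * n_nodes * (n_nodes - 1) / 2 < 1)
    stop("density too low: no edges", call. = FALSE)
  if (weight_min < 0 || weight_max <= weight_min)
    stop("weight bounds must satisfy 0 <= min < max", call. = FALSE)
  groups <- names(n_per_group)
  stopifnot(all(groups %in% names(age_mean)), all(groups %in% names(age_sd)))
  structure(list(n_per_group = n_per_group, n_nodes = as.integer(n_nodes),
                 density = density, weight_mean = weight_mean,
                 weight_sd = weight_sd, weight_min = weight_min,
                 weight_max = weight_max, noise_sd = noise_sd,
                 age_mean = age_mean, age_sd = age_sd, age_min = age_min,
                 sex_prob = sex_prob, groups = groups,
                 control = groups[1]),
            class = "cohort_spec")
}

#' Generate a connected weighted template network
#'
#' Erdos-Renyi topology at a fixed edge count `round(density * n(n-1)/2)`,
#' re-sampled until connected (at most 100 attempts); weights drawn from a
#' truncated normal within the stated bounds.
#'
#' @param n_nodes Node count.
#' @param density Target density in (0, 1].
#' @param weight_mean,weight_sd,weight_min,weight_max Weight distribution.
#' @param seed Integer seed, or `NULL`.
#' @param labels Optional region labels.
#' @return A [weighted_network()].
#' @export
make_template <- function(n_nodes, density, weight_mean = 0.45,
                          weight_sd = 0.1, weight_min = 0.2,
                          weight_max = 0.7, seed = NULL, labels = NULL) {
  if (density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]", call. = FALSE)
  pairs <- .upper_pairs(n_nodes)
  m <- round(density * nrow(pairs))
  if (m < 1) stop("density too low: no edges", call. = FALSE)
  if (density < 2 / n_nodes)
    warning("density below 2/n_nodes; a connected template is unlikely")
  .with_seed(seed, {
    for (attempt in seq_len(100)) {
      take <- sample.int(nrow(pairs), m)
      ei <- pairs[take, 1]
      ej <- pairs[take, 2]
      roots <- .uf_roots(ei, ej, n_nodes)
      if (length(unique(roots)) == 1L) {
        w <- matrix(0, n_nodes, n_nodes)
        wts <- .rtruncnorm(m, weight_mean, weight_sd, weight_min, weight_max)
        w[cbind(ei, ej)] <- wts
        w[cbind(ej, ei)] <- wts
        return(weighted_network(w, labels = labels))
      }
    }
    stop("failed to draw a connected template in 100 attempts ",
         "(density too low?)", call. = FALSE)
  })
}

#' Select a connected subnetwork to plant an effect on
#'
#' Grows a connected edge set of the requested size inside the template by
#' seeded random expansion (start from a random edge, repeatedly add a
#' template edge adjacent to the current node set), so that NBS can recover
#' it as a single cluster.
#'
#' @param template A [weighted_network()].
#' @param n_edges Number of edges to plant.
#' @param seed Integer seed, or `NULL`.
#' @return 2-column matrix of node indices (i < j), one row per edge.
#' @export
plant_subnetwork <- function(template, n_edges = 8, seed = NULL) {
  stopifnot(inherits(template, "weighted_network"))
  pairs <- .upper_pairs(template$n)
  pairs <- pairs[template$weights[pairs] > 0, , drop = FALSE]
  if (n_edges > nrow(pairs))
    stop("template has only ", nrow(pairs), " edges", call. = FALSE)
  .with_seed(seed, {
    chosen <- sample.int(nrow(pairs), 1)
    nodes <- pairs[chosen, ]
    while (length(chosen) < n_edges) {
      touch <- which((pairs[, 1] %in% nodes | pairs[, 2] %in% nodes))
      cand <- setdiff(touch, chosen)
      if (length(cand) == 0)
        stop("cannot grow a connected subnetwork of ", n_edges, " edges",
             call. = FALSE)
      nxt <- if (length(cand) == 1) cand else sample(cand, 1)
      chosen <- c(chosen, nxt)
      nodes <- unique(c(nodes, pairs[nxt, ]))
    }
    pairs[sort(chosen), , drop = FALSE]
  })
}

#' Ground truth for a simulated cohort
#'
#' @param template A [weighted_network()] of population mean weights.
#' @param group_scale Named multiplicative factor on all weights per group;
#'   must be 1 for the control group.
#' @param planted_edges Optional 2-column index matrix of edges carrying a
#'   planted group effect; must be template edges forming one connected
#'   component (see [plant_subnetwork()]).
#' @param planted_deltas Named additive weight offsets per non-control group
#'   applied to the planted edges (control implicitly 0).
#' @param covariate_betas Numeric `c(age, sex)`: additive effect of
#'   (centred) age and of sex on every template edge weight.
#' @param clinical_models Named list of clinical-variable generators; each a
#'   list with `beta` = c(b0, b1, b2, b3) for
#'   `clinical = b0 + b1*measure + b2*age + b3*sex + noise`, `sd` (noise
#'   SD), `measure` (a global measure name, default `total_strength`), and
#'   optionally `groups` (which groups get values; default all non-control).
#' @param control Control group name (default `"HC"`).
#' @param seed Integer seed stored with the truth.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(template,
                         group_scale = c(HC = 1, MS = 0.9, NMOSD = 0.9),
                         planted_edges = NULL,
                         planted_deltas = c(MS = -0.3, NMOSD = -0.15),
                         covariate_betas = c(age = 0, sex = 0),
                         clinical_models = NULL,
                         control = "HC", seed = 1L) {
  stopifnot(inherits(template, "weighted_network"))
  if (!control %in% names(group_scale))
    stop("`group_scale` lacks the control group", call. = FALSE)
  if (abs(group_scale[[control]] - 1) > 1e-12)
    stop("control group scale must be 1", call. = FALSE)
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (any(template$weights[planted_edges] == 0))
      stop("planted edges must be template edges", call. = FALSE)
    nodes <- sort(unique(as.vector(planted_edges)))
    roots <- .uf_roots(planted_edges[, 1], planted_edges[, 2], template$n)
    if (length(unique(roots[nodes])) != 1L)
      stop("planted edges must form one connected component", call. = FALSE)
  }
  structure(list(template = template, group_scale = group_scale,
                 planted_edges = planted_edges,
                 planted_deltas = planted_deltas,
                 covariate_betas = covariate_betas,
                 clinical_models = clinical_models,
                 control = control, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default clinical-score generators
#'
#' EDSS and disease duration linearly and negatively linked to total
#' strength with small age/sex terms — the direction pattern expected for a
#' disabling demyelinating disease (weaker networks, higher disability).
#' Values are left unclipped so coefficient-recovery checks are exact.
#'
#' @return Named list suitable for the `clinical_models` argument of
#'   [ground_truth()].
#' @export
default_clinical_models <- function() {
  list(edss = list(beta = c(10, -0.02, 0.02, 0.2), sd = 0.8,
                   measure = "total_strength"),
       disease_duration = list(beta = c(4, -0.015, 0.15, 0), sd = 2,
                               measure = "total_strength"))
}

# Global measures that clinical models may reference.
.truth_measure <- function(net, name) {
  switch(name,
         total_strength = degree_strength(net)$total_strength,
         network_metrics(net)$global[[name]])
}

#' Simulate a cohort from a spec and a ground truth
#'
#' Subject weights are
#' `clip(template * group_scale + planted_delta + b_age*(age - mean age) +
#' b_sex*sex + noise, 0)` on template edges; non-edges stay zero. Clinical
#' scores are drawn from the linear models in `truth$clinical_models`, using
#' each subject's *realized* network measure, and are `NA` for groups not
#' covered by a model (the control group by default). Generation is a pure
#' function of `(spec, truth, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return List with `cohort` (a [cohort_dataset()]) and `truth`.
#' @export
simulate_cohort <- function(spec, truth, seed = truth$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  if (truth$template$n != spec$n_nodes)
    stop("spec and truth disagree on n_nodes (", spec$n_nodes, " vs ",
         truth$template$n, ")", call. = FALSE)
  missing_scale <- setdiff(spec$groups, names(truth$group_scale))
  if (length(missing_scale))
    stop("`group_scale` lacks group(s): ",
         paste(missing_scale, collapse = ", "), call. = FALSE)
  tw <- truth$template$weights
  pairs <- .upper_pairs(spec$n_nodes)
  epairs <- pairs[tw[pairs] > 0, , drop = FALSE]
  .with_seed(seed, {
    grp <- rep(spec$groups, spec$n_per_group)
    n_sub <- length(grp)
    age <- numeric(n_sub)
    for (g in spec$groups) {
      idx <- grp == g
      age[idx] <- .rtruncnorm(sum(idx), spec$age_mean[[g]], spec$age_sd[[g]],
                              spec$age_min, Inf)
    }
    sex <- rbinom(n_sub, 1, spec$sex_prob)
    agebar <- mean(age)
    ids <- paste0(grp, stats::ave(seq_len(n_sub), grp, FUN = seq_along))
    networks <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      w <- tw * truth$group_scale[[grp[s]]]
      if (!is.null(truth$planted_edges) && grp[s] != truth$control) {
        d <- truth$planted_deltas[[grp[s]]] %||% 0
        w[truth$planted_edges] <- w[truth$planted_edges] + d
        w[truth$planted_edges[, c(2, 1), drop = FALSE]] <-
          w[truth$planted_edges] # keep symmetric
      }
      shift <- truth$covariate_betas[["age"]] * (age[s] - agebar) +
        truth$covariate_betas[["sex"]] * sex[s]
      eps <- if (spec$noise_sd > 0) rnorm(nrow(epairs), 0, spec$noise_sd)
        else 0
      vals <- pmax(w[epairs] + shift + eps, 0)
      w[] <- 0
      w[epairs] <- vals
      w[epairs[, c(2, 1), drop = FALSE]] <- vals
      networks[[s]] <- weighted_network(w, labels = truth$template$labels)
    }
    subjects <- data.frame(subject_id = ids, group = grp, age = age,
                           sex = sex, stringsAsFactors = FALSE)
    for (cl in names(truth$clinical_models)) {
      mod <- truth$clinical_models[[cl]]
      target <- mod$groups %||% setdiff(spec$groups, truth$control)
      vals <- rep(NA_real_, n_sub)
      for (s in which(grp %in% target)) {
        meas <- .truth_measure(networks[[s]],
                               mod$measure %||% "total_strength")
        vals[s] <- mod$beta[1] + mod$beta[2] * meas +
          mod$beta[3] * age[s] + mod$beta[4] * sex[s] +
          if (mod$sd > 0) rnorm(1, 0, mod$sd) else 0
      }
      subjects[[cl]] <- vals
    }
    list(cohort = cohort_dataset(subjects, networks,
                                 control = truth$control,
                                 clinical = names(truth$clinical_models)),
         truth = truth)
  })
}

#' Simulate a null cohort
#'
#' Three (or more) groups drawn from one identical generating distribution:
#' common template, no group scaling, no planted effects, no covariate
#' effects on weights, and a common age distribution (the control group's)
#' for every group — so group labels are exchangeable by construction. Used
#' for type-I-error and FWER calibration.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A [cohort_dataset()].
#' @export
null_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ctrl <- spec$control
  spec$age_mean[] <- spec$age_mean[[ctrl]]
  spec$age_sd[] <- spec$age_sd[[ctrl]]
  template <- make_template(spec$n_nodes, spec$density, spec$weight_mean,
                            spec$weight_sd, spec$weight_min, spec$weight_max,
                            seed = .child_seed(seed, 1))
  scales <- setNames(rep(1, length(spec$groups)), spec$groups)
  truth <- ground_truth(template, group_scale = scales,
                        planted_edges = NULL,
                        planted_deltas = setNames(numeric(0), character(0)),
                        covariate_betas = c(age = 0, sex = 0),
                        clinical_models = NULL, control = ctrl,
                        seed = .child_seed(seed, 2) %||% 1L)
  simulate_cohort(spec, truth, seed = .child_seed(seed, 2))$cohort
}
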