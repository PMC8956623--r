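# Network-based statistics: edge stats, component extraction, permutation
# FWER, post-hoc tables and significance counting.

test_that("edge-wise F equals a direct partial_f call per edge", {
  co <- null_cohort(tiny_spec(n_nodes = 10, n = 8), seed = 211)
  stats <- edgewise_stats(co)
  covs <- cohort_covs(co)
  pairs <- which(upper.tri(stats) & !is.na(stats), arr.ind = TRUE)
  pick <- pairs[seq(1, nrow(pairs), length.out = 12), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    y <- vapply(co$networks, function(n) n$weights[i, j], numeric(1))
    expect_equal(stats[i, j],
                 partial_f(y, co$subjects$group, covs)$statistic,
                 tolerance = 1e-10)
  }
  expect_identical(stats, t(stats))
})

test_that("degenerate edges get F = 0 and huge effects dominate", {
  co <- null_cohort(tiny_spec(n_nodes = 8, n = 6, noise_sd = 0.02),
                    seed = 221)
  # make edge (1,2) identical everywhere and (1,3) equal to the group index
  g_idx <- as.integer(co$subjects$group)
  for (s in seq_along(co$networks)) {
    co$networks[[s]]$weights[1, 2] <- co$networks[[s]]$weights[2, 1] <- 0.4
    co$networks[[s]]$weights[1, 3] <- co$networks[[s]]$weights[3, 1] <-
      g_idx[s] * 0.2
  }
  stats <- edgewise_stats(co)
  expect_equal(stats[1, 2], 0)
  expect_equal(max(stats, na.rm = TRUE), stats[1, 3])
  expect_gt(stats[1, 3], max(stats[-1, -c(1, 3)], na.rm = TRUE))
})

test_that("suprathreshold components match igraph on random stat matrices", {
  for (r in 1:100) {
    set.seed(3000 + r)
    n <- sample(6:15, 1)
    s <- matrix(0, n, n)
    up <- upper.tri(s)
    vals <- rexp(sum(up), rate = 1 / 2)
    s[up] <- vals
    s <- s + t(s)
    diag(s) <- NA
    thr <- runif(1, 0.5, 4)
    comps <- suprathreshold_components(s, thr)

    adj <- !is.na(s) & s >= thr
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::components(g)
    sizes <- table(cl$membership[cl$membership %in%
                                   which(cl$csize > 1)])
    # edge counts per non-trivial igraph component
    ig_extents <- sort(vapply(names(sizes), function(m) {
      nodes <- which(cl$membership == as.integer(m))
      sum(adj[nodes, nodes]) / 2
    }, numeric(1)), decreasing = TRUE)
    expect_equal(vapply(comps, `[[`, numeric(1), "extent"),
                 as.numeric(ig_extents))
    # every reported component is internally connected
    for (comp in comps) {
      sub <- igraph::graph_from_edgelist(comp$edges, directed = FALSE)
      expect_equal(sum(igraph::components(sub)$csize > 1), 1)
    }
  }
})

test_that("no suprathreshold edges yields an empty component list", {
  s <- matrix(0.5, 4, 4); diag(s) <- NA
  expect_identical(suprathreshold_components(s, 3), list())
  expect_error(suprathreshold_components(s, 0), "> 0")
})

test_that("two planted clusters come back sorted with correct extents", {
  s <- matrix(0, 12, 12)
  put <- function(i, j, v) s[i, j] <<- s[j, i] <<- v
  # 5-edge path cluster on nodes 1..6, 3-edge star on 8..11
  for (k in 1:5) put(k, k + 1, 5)
  put(8, 9, 5); put(8, 10, 5); put(8, 11, 5)
  put(2, 9, 1)  # subthreshold bridge must not merge them
  comps <- suprathreshold_components(s, 3)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$extent, 5)
  expect_equal(comps[[2]]$extent, 3)
  expect_equal(comps[[1]]$nodes, 1:6)
  expect_equal(comps[[2]]$nodes, c(8, 9, 10, 11))
})

test_that("raising the threshold never increases any component extent", {
  set.seed(231)
  s <- matrix(0, 14, 14)
  up <- upper.tri(s)
  s[up] <- rexp(sum(up))
  s <- s + t(s); diag(s) <- NA
  thrs <- c(0.5, 1, 2, 3)
  max_ext <- vapply(thrs, function(t) {
    comps <- suprathreshold_components(s, t)
    if (length(comps)) comps[[1]]$extent else 0
  }, numeric(1))
  expect_true(all(diff(max_ext) <= 0))
})

test_that("nbs_test is deterministic and rejects tiny permutation counts", {
  co <- null_cohort(tiny_spec(n_nodes = 12, n = 8), seed = 241)
  cfg <- analysis_config(n_permutations = 150, seed = 3)
  r1 <- nbs_test(co, cfg)
  r2 <- nbs_test(co, cfg)
  expect_identical(summary(r1), summary(r2))
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_error(analysis_config(n_permutations = 50), ">= 100")
})

test_that("a strongly planted connected subnetwork is recovered", {
  tmpl <- make_template(30, 0.5, seed = 251)
  planted <- plant_subnetwork(tmpl, n_edges = 8, seed = 252)
  truth <- ground_truth(tmpl, group_scale = c(HC = 1, MS = 1, NMOSD = 1),
                        planted_edges = planted,
                        planted_deltas = c(MS = -0.3, NMOSD = -0.15),
                        seed = 253)
  co <- simulate_cohort(tiny_spec(n_nodes = 30, n = 15, noise_sd = 0.05),
                        truth)$cohort
  cfg <- analysis_config(nbs_threshold = 8, n_permutations = 300, seed = 4)
  res <- nbs_test(co, cfg, posthoc = FALSE)
  expect_gte(length(res$components), 1)
  sig <- summary(res)
  expect_true(any(sig$significant))
  top <- res$components[[which.min(sig$p_fwer)]]
  key <- function(e) paste(e[, 1], e[, 2])
  jac <- length(intersect(key(top$edges), key(planted))) /
    length(union(key(top$edges), key(planted)))
  expect_gte(jac, 0.8)
})

test_that("post-hoc tables carry one row per edge with sensible nulls", {
  tmpl <- make_template(12, 0.7, seed = 261)
  planted <- plant_subnetwork(tmpl, n_edges = 4, seed = 262)
  truth <- ground_truth(tmpl, group_scale = c(HC = 1, MS = 1, NMOSD = 1),
                        planted_edges = planted,
                        planted_deltas = c(MS = -0.3, NMOSD = 0),
                        seed = 263)
  co <- simulate_cohort(tiny_spec(n_nodes = 12, n = 12, noise_sd = 0.03),
                        truth)$cohort
  cfg <- analysis_config(n_permutations = 200, seed = 5)
  # planted edges plus one unaffected edge
  pairs <- which(upper.tri(tmpl$weights) & tmpl$weights > 0, arr.ind = TRUE)
  key <- paste(pairs[, 1], pairs[, 2])
  null_edge <- pairs[!key %in% paste(planted[, 1], planted[, 2]), ,
                     drop = FALSE][1, , drop = FALSE]
  tab <- posthoc_edges(co, rbind(planted, null_edge), cfg)
  expect_equal(nrow(tab), 5)
  # MS-reduced edges: the MS-vs-HC column is the small one
  expect_true(all(tab$p_fdr_HC_vs_MS[1:4] < 0.05))
  expect_true(all(tab$dir_HC_vs_MS[1:4] == "MS < HC"))
  expect_true(all(tab$p_fdr_HC_vs_NMOSD[1:4] > 0.05))
  expect_error(posthoc_edges(co, planted[0, , drop = FALSE]), "empty")
})

test_that("significance counting on the bundled reference table", {
  ref <- reference_posthoc_table()
  s1 <- ref[ref$subnetwork == 1, ]
  s2 <- ref[ref$subnetwork == 2, ]
  expect_equal(nrow(s1), 29)
  expect_equal(nrow(s2), 5)
  expect_equal(count_significant(s1, "p_ms_lt_hc"), 28)
  expect_equal(count_significant(s1, "p_nmosd_lt_hc"), 13)
  expect_equal(count_significant(s2, "p_ms_lt_nmosd"), 4)
  expect_error(count_significant(s1, "nope"), "unknown column")
})
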