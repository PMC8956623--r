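# The synthetic cohort generator: template topology, group effects,
# covariates, clinical linkage, determinism.

test_that("templates hit the target edge count, stay connected, repeat under a seed", {
  t1 <- make_template(90, 0.6, seed = 1)
  m <- sum(t1$weights[upper.tri(t1$weights)] > 0)
  expect_lte(abs(m - 2403), 2)
  expect_equal(igraph::components(igraph::graph_from_adjacency_matrix(
    t1$weights > 0, mode = "undirected"))$no, 1)
  w <- t1$weights[upper.tri(t1$weights)]
  expect_true(all(w[w > 0] >= 0.2 & w[w > 0] <= 0.7))

  t2 <- make_template(90, 0.6, seed = 1)
  expect_identical(t1$weights, t2$weights)

  full <- make_template(10, 1, seed = 2)
  expect_equal(sum(full$weights[upper.tri(full$weights)] > 0), 45)

  expect_warning(expect_error(make_template(30, 0.02, seed = 3),
                              "connected"),
                 "unlikely")
})

test_that("noise-free group scaling is exactly linear", {
  tmpl <- make_template(12, 0.6, seed = 21)
  truth <- ground_truth(tmpl, group_scale = c(HC = 1, MS = 0.9, NMOSD = 0.9),
                        seed = 22)
  res <- simulate_cohort(tiny_spec(n_nodes = 12, n = 3, noise_sd = 0),
                         truth)
  co <- res$cohort
  s <- total_strengths(co)
  grp <- co$subjects$group
  expect_equal(unname(s[grp == "MS"]),
               rep(unname(0.9 * s[grp == "HC"][1]), 3), tolerance = 1e-12)
  expect_equal(unname(s[grp == "NMOSD"]),
               rep(unname(0.9 * s[grp == "HC"][1]), 3), tolerance = 1e-12)
})

test_that("planted deltas touch exactly the planted edges", {
  tmpl <- make_template(12, 0.6, seed = 31)
  planted <- plant_subnetwork(tmpl, n_edges = 5, seed = 32)
  truth <- ground_truth(tmpl, group_scale = c(HC = 1, MS = 1, NMOSD = 1),
                        planted_edges = planted,
                        planted_deltas = c(MS = -0.1, NMOSD = 0),
                        seed = 33)
  co <- simulate_cohort(tiny_spec(n_nodes = 12, n = 2, noise_sd = 0),
                        truth)$cohort
  grp <- co$subjects$group
  w_hc <- co$networks[[which(grp == "HC")[1]]]$weights
  w_ms <- co$networks[[which(grp == "MS")[1]]]$weights
  diff <- abs(w_hc - w_ms) > 1e-12
  expect_equal(sum(diff[upper.tri(diff)]), 5)
  expect_true(all(diff[planted]))
  expect_equal(w_ms[planted], w_hc[planted] - 0.1, tolerance = 1e-12)
})

test_that("planted subnetworks are connected template edges", {
  tmpl <- make_template(20, 0.4, seed = 41)
  planted <- plant_subnetwork(tmpl, n_edges = 8, seed = 42)
  expect_equal(nrow(planted), 8)
  expect_true(all(tmpl$weights[planted] > 0))
  g <- igraph::graph_from_edgelist(planted, directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(sum(comp$csize > 1), 1)
  # edges not in the template are rejected
  absent <- which(upper.tri(tmpl$weights) & tmpl$weights == 0,
                  arr.ind = TRUE)[1, , drop = FALSE]
  expect_error(ground_truth(tmpl, planted_edges = absent, seed = 1),
               "template edges")
})

test_that("noise-free clinical scores follow the stated linear model exactly", {
  tmpl <- make_template(10, 0.7, seed = 51)
  truth <- ground_truth(
    tmpl, group_scale = c(HC = 1, MS = 1, NMOSD = 1),
    clinical_models = list(score = list(beta = c(0, 2, 0.1, 0), sd = 0,
                                        measure = "total_strength")),
    seed = 52)
  co <- simulate_cohort(tiny_spec(n_nodes = 10, n = 4, noise_sd = 0.03),
                        truth)$cohort
  dis <- co$subjects$group != "HC"
  expected <- 2 * total_strengths(co)[dis] + 0.1 * co$subjects$age[dis]
  expect_equal(unname(co$subjects$score[dis]), unname(expected),
               tolerance = 1e-10)
  expect_true(all(is.na(co$subjects$score[!dis])))
})

test_that("generation is a pure function of (spec, truth, seed)", {
  spec <- tiny_spec(n_nodes = 10, n = 3)
  tmpl <- make_template(10, 0.6, seed = 61)
  truth <- ground_truth(tmpl, clinical_models = default_clinical_models(),
                        seed = 62)
  c1 <- simulate_cohort(spec, truth)$cohort
  c2 <- simulate_cohort(spec, truth)$cohort
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(lapply(c1$networks, `[[`, "weights"),
                   lapply(c2$networks, `[[`, "weights"))
})

test_that("generated networks always satisfy the network invariants", {
  res <- simulate_cohort(tiny_spec(n_nodes = 14, n = 5, noise_sd = 0.3),
                         ground_truth(make_template(14, 0.5, seed = 71),
                                      group_scale = c(HC = 1, MS = 0.7,
                                                      NMOSD = 0.85),
                                      seed = 72))
  for (net in res$cohort$networks) {
    expect_true(all(net$weights >= 0))
    expect_identical(net$weights, t(net$weights))
    expect_true(all(diag(net$weights) == 0))
    # zero template edges stay zero even under heavy noise
    expect_true(all(net$weights[res$truth$template$weights == 0] == 0))
  }
})

test_that("null cohorts give every group the same generating distribution", {
  co <- null_cohort(tiny_spec(n_nodes = 10, n = 20), seed = 81)
  ages <- split(co$subjects$age, co$subjects$group)
  # same age distribution for all groups: crude scale check only
  expect_lt(abs(mean(ages$MS) - mean(ages$HC)), 10)
  expect_lt(abs(mean(ages$NMOSD) - mean(ages$HC)), 10)
  # weights carry no group information: per-group mean totals are close
  s <- split(total_strengths(co), co$subjects$group)
  m <- vapply(s, mean, numeric(1))
  expect_lt(diff(range(m)) / mean(m), 0.05)
})

test_that("spec/truth dimension mismatches are rejected", {
  spec <- tiny_spec(n_nodes = 10)
  truth <- ground_truth(make_template(12, 0.6, seed = 91), seed = 92)
  expect_error(simulate_cohort(spec, truth), "n_nodes")
  expect_error(ground_truth(make_template(5, 0.9, seed = 1),
                            group_scale = c(HC = 2, MS = 1, NMOSD = 1)),
               "control group scale")
})
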