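# Weighted topology measures against hand computations and independent
# brute-force oracles.

test_that("degree, strength and total strength match hand counts", {
  net <- path3_net()
  ds <- degree_strength(net)
  expect_equal(unname(ds$degree), c(1L, 2L, 1L))
  expect_equal(unname(ds$strength), c(0.5, 1.0, 0.5))
  expect_equal(ds$total_strength, 2.0)

  empty <- weighted_network(matrix(0, 4, 4))
  ds0 <- degree_strength(empty)
  expect_true(all(ds0$degree == 0) && all(ds0$strength == 0))
  expect_equal(ds0$total_strength, 0)
})

test_that("clustering matches the triangle example and zero cases", {
  k3 <- complete_net(3, 0.5)
  cc <- clustering_coef(k3)
  expect_equal(unname(cc$triangle_intensity), rep(0.5, 3))
  expect_equal(unname(cc$nodal), rep(0.5, 3))
  expect_equal(cc$global, 0.5)

  # star graph: no triangles anywhere
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- w[2:5, 1] <- 0.4
  expect_equal(unname(clustering_coef(weighted_network(w))$nodal), rep(0, 5))
})

test_that("shortest paths use reciprocal weights and flag disconnection", {
  net <- path3_net()
  d <- shortest_paths_matrix(net)
  expect_equal(d[1, 2], 2)
  expect_equal(d[2, 3], 2)
  expect_equal(d[1, 3], 4)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  d2 <- shortest_paths_matrix(weighted_network(w))
  expect_identical(d2[1, 3], Inf)
  # infinite pairs are ignored in the average
  expect_equal(characteristic_path_length(d2), 2)
})

test_that("characteristic path length, efficiencies match hand computations", {
  d <- shortest_paths_matrix(path3_net())
  expect_equal(characteristic_path_length(d), 8 / 3)
  expect_equal(global_efficiency(d), (0.375 + 0.5 + 0.375) / 3)
  expect_equal(unname(regional_efficiency(d)), c(0.375, 0.5, 0.375))

  expect_error(characteristic_path_length(
    shortest_paths_matrix(weighted_network(matrix(0, 3, 3)))),
    "disconnected")
  expect_equal(global_efficiency(
    shortest_paths_matrix(weighted_network(matrix(0, 3, 3)))), 0)
})

test_that("local efficiency handles degenerate subgraphs and symmetry", {
  # path: end nodes have K<2, centre's neighbour subgraph has no edge
  expect_equal(unname(local_efficiency(path3_net())$nodal), c(0, 0, 0))
  # K3 with equal weights: all nodes identical by symmetry
  le <- local_efficiency(complete_net(3, 0.5))$nodal
  expect_equal(unname(le), rep(le[[1]], 3))
})

test_that("complete unit-weight graphs hit the closed-form limits exactly", {
  for (n in c(4, 7)) {
    m <- network_metrics(complete_net(n))
    expect_identical(unname(m$global["total_strength"]), as.numeric(n * (n - 1)))
    expect_identical(unname(m$global["clustering_coef"]), 1)
    expect_identical(unname(m$global["char_path_length"]), 1)
    expect_identical(unname(m$global["local_efficiency"]), 1)
    expect_identical(unname(m$global["global_efficiency"]), 1)
  }
})

test_that("all metrics agree with brute-force oracles on random networks", {
  for (r in 1:50) {
    n <- sample(5:12, 1)
    w <- rand_weights(n, density = runif(1, 0.3, 0.9), seed = 100 + r)
    net <- weighted_network(w)

    ds <- degree_strength(net)
    o <- oracle_degree_strength(w)
    expect_equal(unname(ds$degree), o$degree)
    expect_lt(max(abs(ds$strength - o$strength)), 1e-10)
    expect_lt(abs(ds$total_strength - o$total), 1e-10)

    cc <- clustering_coef(net)
    oc <- oracle_clustering(w)
    expect_lt(max(abs(cc$triangle_intensity - oc$triangle_intensity)), 1e-10)
    expect_lt(max(abs(cc$nodal - oc$nodal)), 1e-10)

    d <- shortest_paths_matrix(net)
    od <- oracle_distances(w)
    expect_lt(max(abs(d - od), na.rm = TRUE), 1e-10)
    expect_identical(unname(is.infinite(d)), is.infinite(od))

    le <- local_efficiency(net)
    ole <- oracle_local_efficiency(w)
    expect_lt(max(abs(le$nodal - ole)), 1e-10)
  }
})

test_that("removing an edge is monotone for K, S, t, E_glob and distances", {
  for (r in 1:10) {
    w <- rand_weights(9, density = 0.6, seed = 300 + r)
    net <- weighted_network(w)
    present <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    pick <- present[sample(nrow(present), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 0
    net2 <- weighted_network(w2)

    expect_true(all(degree_strength(net2)$degree <=
                      degree_strength(net)$degree))
    expect_true(all(degree_strength(net2)$strength <=
                      degree_strength(net)$strength + 1e-12))
    expect_true(all(clustering_coef(net2)$triangle_intensity <=
                      clustering_coef(net)$triangle_intensity + 1e-12))
    d1 <- shortest_paths_matrix(net)
    d2 <- shortest_paths_matrix(net2)
    expect_true(all(d2 - d1 >= -1e-12))
    expect_lte(global_efficiency(d2), global_efficiency(d1) + 1e-12)
  }
})

test_that("strengthening an edge never decreases global efficiency", {
  for (r in 1:10) {
    w <- rand_weights(9, density = 0.5, seed = 400 + r)
    present <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    pick <- present[sample(nrow(present), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- w[pick[1], pick[2]] + 0.3
    e1 <- global_efficiency(shortest_paths_matrix(weighted_network(w)))
    e2 <- global_efficiency(shortest_paths_matrix(weighted_network(w2)))
    expect_gte(e2, e1 - 1e-12)
  }
})

test_that("metrics scale correctly under weight homogeneity", {
  w <- rand_weights(10, density = 0.6, seed = 77)
  net <- weighted_network(w)
  netc <- weighted_network(0.5 * w)
  m1 <- network_metrics(net)
  m2 <- network_metrics(netc)
  expect_identical(m1$nodal$degree, m2$nodal$degree)
  expect_equal(m2$global[["total_strength"]],
               0.5 * m1$global[["total_strength"]])
  expect_equal(m2$global[["char_path_length"]],
               2 * m1$global[["char_path_length"]])
  expect_equal(m2$global[["global_efficiency"]],
               0.5 * m1$global[["global_efficiency"]])
})

test_that("metric-set invariants hold on a simulated subject", {
  net <- simulate_cohort(tiny_spec(n_nodes = 15, n = 1),
                         ground_truth(make_template(15, 0.5, seed = 8),
                                      seed = 8))$cohort$networks[[1]]
  m <- network_metrics(net)
  expect_true(all(m$nodal$degree >= 0 & m$nodal$degree <= net$n - 1))
  expect_true(all(m$nodal$strength >= 0))
  expect_true(all(m$nodal$clustering >= 0 & m$nodal$clustering <= 1))
  expect_equal(sum(m$nodal$strength), m$global[["total_strength"]])
  expect_true(all(m$nodal$local_efficiency >= 0))
  expect_true(all(m$nodal$regional_efficiency >= 0))
})
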