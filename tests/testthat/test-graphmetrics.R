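test_that("hand-computed values on canonical small graphs", {
  p3 <- make_net(path_graph(3))
  k6 <- make_net(complete_graph(6))
  k3 <- make_net(complete_graph(3))
  k4 <- make_net(complete_graph(4))
  star <- make_net(star_graph(3))

  d <- shortest_path_matrix(p3)
  expect_equal(d[1, 3], 2)
  expect_true(all(shortest_path_matrix(k6)[row(diag(6)) != col(diag(6))] == 1))

  expect_equal(mean(clustering_coefficient(k3)), 1)
  expect_equal(mean(clustering_coefficient(star)), 0)

  expect_equal(characteristic_path_length(p3)$Lp, 4 / 3)
  expect_equal(characteristic_path_length(k6)$Lp, 1)

  expect_equal(global_efficiency(k6), 1)
  expect_equal(global_efficiency(p3), 5 / 6)

  expect_equal(local_efficiency(k4), 1)   # neighbor subgraphs are triangles
  expect_equal(local_efficiency(star), 0) # edgeless neighbor subgraphs

  en <- nodal_efficiency(p3)
  expect_equal(unname(en[2]), 1)     # middle node: (1 + 1)/2
  expect_equal(unname(en[1]), 0.75)  # end node: (1 + 1/2)/2
  expect_true(all(nodal_efficiency(k6) == 1))
})

test_that("ring-lattice clustering matches the closed form 3(k-2)/(4(k-1))", {
  net <- make_net(ring_lattice(100, 6))
  expect_equal(mean(clustering_coefficient(net)), 3 * 4 / (4 * 5))
  expect_equal(mean(clustering_coefficient(net)), 0.6)
})

test_that("metrics match brute-force oracles on random graphs", {
  for (s in 1:100) {
    n <- sample(5:15, 1)
    a <- random_adj(n, runif(1, 0.15, 0.6), seed = s)
    net <- make_net(a)
    expect_equal(shortest_path_matrix(net), fw_distances(a),
                 ignore_attr = TRUE)
    expect_equal(unname(clustering_coefficient(net)), clustering_oracle(a),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), global_eff_oracle(a),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(net), local_eff_oracle(a),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(net)), nodal_eff_oracle(a),
                 tolerance = 1e-12)
    if (any(is.finite(fw_distances(a)[upper.tri(a)])))
      expect_equal(characteristic_path_length(net)$Lp, lp_oracle(a),
                   tolerance = 1e-12)
  }
})

test_that("mean nodal efficiency equals global efficiency on every graph", {
  for (s in 1:30) {
    a <- random_adj(sample(6:20, 1), runif(1, 0.1, 0.7), seed = 1000 + s)
    expect_equal(mean(nodal_efficiency(make_net(a))),
                 global_efficiency(make_net(a)), tolerance = 1e-12)
  }
})

test_that("fragmentation is reported, not fatal, and efficiency uses 1/Inf = 0", {
  # two disjoint triangles plus an isolated node
  a <- matrix(0L, 7, 7)
  a[1:3, 1:3] <- 1L; a[4:6, 4:6] <- 1L
  diag(a) <- 0L
  net <- make_net(a)
  res <- characteristic_path_length(net)
  expect_true(res$fragmented)
  expect_equal(res$Lp, 1)  # finite pairs are all within-triangle
  expect_equal(res$infinite_pairs, 3 * 3 + 6)
  en <- nodal_efficiency(net)
  expect_equal(unname(en[7]), 0)           # isolated node scores 0
  expect_true(all(en[1:6] > 0))
  expect_equal(global_efficiency(net), mean(en), tolerance = 1e-12)
})

test_that("adding an edge never decreases global efficiency", {
  for (s in 1:10) {
    a <- random_adj(10, 0.3, seed = 40 + s)
    e0 <- global_efficiency(make_net(a))
    absent <- which(upper.tri(a) & a == 0)
    if (length(absent) == 0) next
    idx <- absent[1]
    b <- a
    b[idx] <- 1L
    b <- pmax(b, t(b))
    expect_gte(global_efficiency(make_net(b)), e0)
  }
})

test_that("scalar metrics are invariant under node permutation", {
  a <- random_adj(12, 0.35, seed = 99)
  set.seed(1)
  p <- sample(12)
  b <- a[p, p]
  expect_equal(global_efficiency(make_net(a)), global_efficiency(make_net(b)),
               tolerance = 1e-12)
  expect_equal(local_efficiency(make_net(a)), local_efficiency(make_net(b)),
               tolerance = 1e-12)
  expect_equal(mean(clustering_coefficient(make_net(a))),
               mean(clustering_coefficient(make_net(b))), tolerance = 1e-12)
  expect_equal(characteristic_path_length(make_net(a))$Lp,
               characteristic_path_length(make_net(b))$Lp, tolerance = 1e-12)
})

test_that("metrics cross-check against igraph on a random graph", {
  a <- random_adj(25, 0.25, seed = 7)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_equal(unname(shortest_path_matrix(make_net(a))),
               unname(igraph::distances(g)))
  expect_equal(unname(clustering_coefficient(make_net(a))),
               ifelse(is.nan(tr <- igraph::transitivity(g, type = "local")),
                      0, tr),
               tolerance = 1e-12)
})

test_that("global_metrics and curves assemble tidy tables", {
  z <- cor(matrix(rnorm(40 * 12), 40, 12))
  diag(z) <- 0
  sw <- sweep_costs(z, c(0.2, 0.3))
  curves <- metric_curves(sw)
  expect_equal(nrow(curves), 2)
  expect_named(curves, c("subject_id", "cost", "Cp", "Lp", "Eglobal",
                         "Elocal", "infinite_pairs", "fragmented"))
  nc <- nodal_curves(sw)
  expect_equal(nrow(nc), 2 * 12)
  expect_true(all(nc$degree[nc$cost == 0.3] >= 0))
})
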