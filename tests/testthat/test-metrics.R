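test_that("density is the weight sum over possible edges", {
  E <- matrix(c(0, 0.5, 1, 0), 2, 2)
  expect_equal(net_density(agg_network(E)), 0.75)
  expect_equal(net_density(agg_network(matrix(0, 3, 3))), 0)
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(net_density(agg_network(K3)), 1)
  expect_error(net_density(matrix(0, 1, 1)), "2 nodes")
})

test_that("transitivity handles the canonical binary cases", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  expect_equal(net_transitivity(agg_network(tri)), 1)
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(net_transitivity(agg_network(path)), 0)
  expect_warning(val <- net_transitivity(agg_network(matrix(0, 3, 3))),
                 "no connected triplets")
  expect_equal(val, 0)
  # binary case agrees with igraph's global transitivity
  set.seed(42)
  A <- (matrix(runif(64), 8, 8) < 0.4) * 1
  A <- ((A + t(A)) > 0) * 1; diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(net_transitivity(A), igraph::transitivity(g, type = "global"))
})

test_that("weighted transitivity equals exhaustive triplet enumeration", {
  for (s in 1:10) {
    net <- rand_net(6, 0.5, seed = s)
    expect_equal(net_transitivity(net), brute_transitivity(net$E))
  }
})

test_that("strength correlation matches a direct Pearson computation", {
  sym <- rand_net(8, 0.6, seed = 2)$E
  sym <- (sym + t(sym)) / 2
  expect_equal(strength_correlation(agg_network(pmin(sym, 1))), 1)
  for (s in 1:5) {
    E <- rand_net(10, 0.5, seed = 100 + s)$E
    si <- colSums(E); so <- rowSums(E)
    want <- sum((si - mean(si)) * (so - mean(so))) /
      sqrt(sum((si - mean(si))^2) * sum((so - mean(so))^2))
    expect_equal(strength_correlation(agg_network(E)), want)
  }
  expect_warning(v <- strength_correlation(agg_network(matrix(0, 3, 3))),
                 "constant")
  expect_true(is.na(v))
})

test_that("effective distances follow 1 - ln of the row-standardized weights", {
  E <- matrix(0, 3, 3)
  E[1, 2] <- 0.7                 # single out-edge: P = 1, ED = 1
  E[2, 1] <- 0.3; E[2, 3] <- 0.3 # split row: P = 0.5 each
  ED <- effective_distances(agg_network(E))
  expect_equal(ED[1, 2], 1)
  expect_equal(ED[2, 1], 1 - log(0.5))
  expect_equal(ED[2, 3], 1 - log(0.5))
  expect_true(all(is.infinite(ED[3, ])))  # zero row: no way out
  expect_true(all(ED[is.finite(ED)] >= 1))
  # invariant to global rescaling of the weights
  expect_equal(effective_distances(agg_network(E * 0.2)), ED)
})

test_that("shortest-path stats match hand computation and Floyd-Warshall", {
  ED <- matrix(Inf, 3, 3)
  ED[1, 2] <- 1; ED[2, 3] <- 1
  sp <- shortest_path_stats(ED)
  expect_equal(sp$diameter, 2)
  expect_equal(sp$average_shortest_path, 4 / 3)
  expect_equal(sp$unreachable_pairs, 3)

  one <- matrix(Inf, 2, 2); one[1, 2] <- 3.7
  sp1 <- shortest_path_stats(one)
  expect_equal(sp1$diameter, 3.7)
  expect_equal(sp1$average_shortest_path, 3.7)

  for (s in 1:10) {
    net <- rand_net(8, 0.35, seed = 200 + s)
    ED <- effective_distances(net)
    got <- shortest_path_stats(ED)
    D <- fw_oracle(ED)
    off <- D[row(D) != col(D)]
    expect_equal(got$diameter, max(off[is.finite(off)]))
    expect_equal(got$average_shortest_path, mean(off[is.finite(off)]))
    expect_equal(got$unreachable_pairs, sum(!is.finite(off)))
    expect_gte(got$diameter, got$average_shortest_path)
    expect_gte(got$average_shortest_path, 1)
  }
  expect_error(shortest_path_stats(matrix(Inf, 3, 3)), "disconnected")
})

test_that("edge removal only ever destroys reachability, never creates it", {
  for (s in 1:5) {
    net <- rand_net(9, 0.6, seed = 300 + s)
    E2 <- net$E
    set.seed(s)
    E2[sample(which(E2 > 0), 5)] <- 0
    D1 <- fw_oracle(effective_distances(net))
    D2 <- fw_oracle(effective_distances(agg_network(E2)))
    reach2 <- is.finite(D2) & row(D2) != col(D2)
    expect_true(all(is.finite(D1)[reach2]))
  }
})

test_that("weight-distance correlation is -1 for linear decay and NA when degenerate", {
  nodes <- data.frame(id = 1:4, lon = c(0, 1, 2, 3), lat = 40)
  dm <- centroid_distances(nodes)
  E <- 1 - dm / (2 * max(dm)); diag(E) <- 0
  net <- agg_network(E, nodes = nodes)
  expect_equal(weight_distance_correlation(net), -1, tolerance = 1e-9)
  Ec <- (dm > 0) * 0.5
  expect_warning(v <- weight_distance_correlation(agg_network(Ec, nodes = nodes)),
                 "zero variance")
  expect_true(is.na(v))
})

test_that("the metric report carries the five metrics for a labelled network", {
  net <- rand_net(7, 0.5, seed = 17, coords = TRUE, label = "July")
  m <- network_metrics(net)
  expect_identical(names(m), c("label", "diameter", "density", "transitivity",
                               "strength_correlation", "average_shortest_path"))
  expect_identical(m$label, "July")
  expect_true(m$density >= 0 && m$density <= 1)
  expect_true(m$transitivity >= 0 && m$transitivity <= 1)
})
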