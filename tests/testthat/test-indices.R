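test_that("total degree is graph density", {
  expect_equal(total_degree(graph_from_adjacency(complete_adjacency(40))), 1)
  expect_equal(total_degree(graph_from_adjacency(matrix(FALSE, 5, 5))), 0)
  expect_equal(total_degree(graph_from_adjacency(path_adjacency(3))), 2 / 3)
  expect_error(total_degree(graph_from_points(matrix(0, 1, 2), d = 1)))
})

test_that("total edge length is normalized by its maximum possible value", {
  # 3-4-5 triangle at d = 5: all 3 possible edges present
  g <- graph_from_points(rbind(c(0, 0), c(3, 0), c(0, 4)), d = 5)
  expect_equal(total_edge_length(g), 12 / (2 * 5 * 3))
  # two points at distance exactly d: the maximum 0.5
  g2 <- graph_from_points(rbind(c(0, 0), c(5, 0)), d = 5)
  expect_equal(total_edge_length(g2), 0.5)
  # edgeless
  g3 <- graph_from_points(rbind(c(0, 0), c(50, 0)), d = 5)
  expect_equal(total_edge_length(g3), 0)
  # partial graph: sum over present edges only, max-edges divisor
  g4 <- graph_from_points(rbind(c(0, 0), c(5, 0), c(100, 0)), d = 6)
  expect_equal(total_edge_length(g4), 5 / (2 * 6 * 3))
})

test_that("connected components index covers its limits", {
  expect_equal(connected_components_index(
    graph_from_adjacency(matrix(FALSE, 7, 7))), 1)
  expect_equal(connected_components_index(
    graph_from_adjacency(complete_adjacency(8))), 1 / 8)
})

test_that("exact solvers match exhaustive enumeration on small graphs", {
  set.seed(271)
  for (rep in 1:40) {
    n <- sample(4:11, 1)
    A <- random_adjacency(n, stats::runif(1, 0.1, 0.7))
    g <- graph_from_adjacency(A)
    expect_equal(clique_number_index(g) * n, brute_clique_number(A))
    expect_equal(independence_number_index(g) * n, brute_independence_number(A))
    expect_equal(domination_number_index(g) * n, brute_domination_number(A))
  }
})

test_that("clique, domination and independence handle canonical graphs", {
  expect_equal(clique_number_index(graph_from_adjacency(complete_adjacency(9))), 1)
  expect_equal(clique_number_index(graph_from_adjacency(matrix(FALSE, 6, 6))), 1 / 6)
  expect_equal(domination_number_index(graph_from_adjacency(matrix(FALSE, 6, 6))), 1)
  expect_equal(domination_number_index(graph_from_adjacency(star_adjacency(9))), 1 / 9)
  expect_equal(domination_number_index(graph_from_adjacency(cycle_adjacency(6))), 2 / 6)
  expect_equal(independence_number_index(graph_from_adjacency(matrix(FALSE, 5, 5))), 1)
  expect_equal(independence_number_index(graph_from_adjacency(complete_adjacency(5))), 1 / 5)
  expect_equal(independence_number_index(graph_from_adjacency(cycle_adjacency(5))), 2 / 5)
})

test_that("clustering coefficients follow the per-vertex and triplet formulas", {
  tri <- graph_from_adjacency(complete_adjacency(3))
  expect_equal(local_clustering_index(tri), 1)
  expect_equal(global_clustering_index(tri), 1)
  p3 <- graph_from_adjacency(path_adjacency(3))
  expect_equal(local_clustering_index(p3), 0)
  star <- graph_from_adjacency(star_adjacency(5))
  expect_equal(global_clustering_index(star), 0)
  # K4 minus one edge: lc = (2/3, 2/3, 1, 1)/4; gc = 3*2/8
  A <- complete_adjacency(4); A[1, 2] <- A[2, 1] <- FALSE
  km <- graph_from_adjacency(A)
  expect_equal(local_clustering_index(km), 5 / 6)
  expect_equal(global_clustering_index(km), 0.75)
})

test_that("order relations hold on generated graphs: DN <= IN, CC <= IN", {
  set.seed(99)
  for (rep in 1:12) {
    cf <- generate_pattern(sample(10:20, 1), seed = 400 + rep)
    g <- build_graph(cf, stats::runif(1, 10, 200))
    dn <- domination_number_index(g)
    cc <- connected_components_index(g)
    inx <- independence_number_index(g)
    expect_lte(dn, inx)
    expect_lte(cc, inx)
  }
})

test_that("combinatorial indices are monotone in d on a fixed pattern", {
  cf <- generate_pattern(18, seed = 55)
  ds <- c(15, 30, 60, 120, 240, 320)
  gs <- lapply(ds, function(d) build_graph(cf, d))
  td <- vapply(gs, total_degree, 0)
  cl <- vapply(gs, clique_number_index, 0)
  cc <- vapply(gs, connected_components_index, 0)
  dn <- vapply(gs, domination_number_index, 0)
  inx <- vapply(gs, independence_number_index, 0)
  expect_true(all(diff(td) >= 0))
  expect_true(all(diff(cl) >= 0))
  expect_true(all(diff(cc) <= 0))
  expect_true(all(diff(dn) <= 0))
  expect_true(all(diff(inx) <= 0))
})

test_that("random-walk index matches the coupon-collector law on K_n", {
  # K_2: the walk covers in exactly one step from either start
  k2 <- graph_from_adjacency(complete_adjacency(2))
  v2 <- random_walk_index(k2, walks = 40, seed = 1)
  expect_equal(as.numeric(v2), 2 * log(2))
  expect_equal(attr(v2, "mc_error"), 0)
  # K_20: mean cover time (n-1) H_{n-1}
  k20 <- graph_from_adjacency(complete_adjacency(20))
  v <- random_walk_index(k20, walks = 2000, seed = 8)
  pred <- 20 * log(20) / kn_cover_time(20)
  expect_lt(abs(as.numeric(v) - pred), 3 * attr(v, "mc_error") + 1e-12)
  # disconnected graphs score zero
  disc <- graph_from_points(rbind(c(0, 0), c(100, 0), c(101, 0)), d = 5)
  expect_equal(as.numeric(random_walk_index(disc, walks = 10, seed = 1)), 0)
})

test_that("random-walk index is reproducible bit-for-bit under a seed", {
  cf <- generate_pattern(25, seed = 12)
  g <- build_graph(cf, 120)
  a <- random_walk_index(g, walks = 200, seed = 77)
  b <- random_walk_index(g, walks = 200, seed = 77)
  expect_identical(a, b)
})

test_that("eigenvector centrality recovers exact dominant eigenvectors", {
  # single edge: degree start is already the eigenvector
  k2 <- graph_from_adjacency(complete_adjacency(2))
  expect_equal(eigenvector_centrality_index(k2), 1 / sqrt(2), tolerance = 1e-5)
  # complete K4: uniform Perron vector, mean = 1/sqrt(4)
  k4 <- graph_from_adjacency(complete_adjacency(4))
  expect_equal(eigenvector_centrality_index(k4), 0.5, tolerance = 1e-5)
  # vertex-transitive cycle: 1/sqrt(n)
  c8 <- graph_from_adjacency(cycle_adjacency(8))
  expect_equal(eigenvector_centrality_index(c8), 1 / sqrt(8), tolerance = 1e-4)
  # disconnected graph: missing by the connectivity gate
  disc <- graph_from_points(rbind(c(0, 0), c(100, 0)), d = 5)
  expect_true(is.na(eigenvector_centrality_index(disc)))
  # whole-graph mode settles on the dominant component
  two <- graph_from_points(rbind(c(0, 0), c(4, 0), c(2, 3), c(100, 0), c(104, 0)),
                           d = 5)
  v <- eigenvector_centrality_index(two, connected_only = FALSE)
  expect_equal(v, 3 * (1 / sqrt(3)) / 5, tolerance = 1e-4)  # triangle dominates
  # edgeless graph: zero start vector, no convergence
  empt <- graph_from_adjacency(matrix(FALSE, 4, 4))
  expect_equal(eigenvector_centrality_index(empt, connected_only = FALSE), 0)
})

test_that("compute_indices matches individual calls and the known limits", {
  k40 <- graph_from_adjacency(complete_adjacency(40))
  res <- compute_indices(k40, indices = c("TD", "CC", "CL", "DN", "IN", "LC", "GC"))
  vals <- stats::setNames(res$value, res$index)
  expect_equal(unname(vals[c("TD", "CL", "LC", "GC")]), rep(1, 4))
  expect_equal(unname(vals[c("CC", "DN", "IN")]), rep(1 / 40, 3))
  # edgeless graph limits
  e22 <- graph_from_adjacency(matrix(FALSE, 22, 22))
  res0 <- compute_indices(e22, indices = c("TD", "TL", "CC", "DN", "IN", "LC", "GC", "RW"))
  v0 <- stats::setNames(res0$value, res0$index)
  expect_equal(unname(v0[c("TD", "TL", "LC", "GC", "RW")]), rep(0, 5))
  expect_equal(unname(v0[c("CC", "DN", "IN")]), rep(1, 3))
  # self-consistency on a generated pattern
  cf <- generate_pattern(20, seed = 31)
  g <- build_graph(cf, 80)
  res2 <- compute_indices(g, indices = c("TD", "CC", "CL", "OC"), seed = 4)
  expect_equal(res2$value[res2$index == "TD"], total_degree(g))
  expect_equal(res2$value[res2$index == "CC"], connected_components_index(g))
  expect_equal(res2$value[res2$index == "CL"], clique_number_index(g))
  expect_equal(res2$value[res2$index == "OC"], occupancy_analytic(cf, 80)$value)
  # failed cells are flagged, not fatal: CL on a 1-vertex graph
  one <- graph_from_points(matrix(0, 1, 2), d = 1)
  resf <- compute_indices(one, indices = c("TD", "CC"))
  expect_true(is.na(resf$value[resf$index == "TD"]))
  expect_match(resf$note[resf$index == "TD"], "n < 2")
  expect_equal(resf$value[resf$index == "CC"], 1)
})

test_that("index values respect their normalized ranges on random graphs", {
  set.seed(606)
  for (rep in 1:6) {
    cf <- generate_pattern(15, seed = 700 + rep)
    g <- build_graph(cf, stats::runif(1, 10, 320))
    res <- compute_indices(g, indices = setdiff(INDEX_NAMES, c("RW", "EG")),
                           seed = rep)
    v <- stats::setNames(res$value, res$index)
    expect_true(all(v[c("TD", "CC", "CL", "DN", "IN", "LC", "GC")] >= 0))
    expect_true(all(v[c("TD", "CC", "CL", "DN", "IN", "LC", "GC")] <= 1))
    expect_gte(v[["TL"]], 0)
    expect_lte(v[["TL"]], 0.5)
    expect_gt(v[["OC"]], 0)
    expect_lte(v[["OC"]], 1 + 1e-12)
  }
})
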