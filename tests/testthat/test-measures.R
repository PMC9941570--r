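# modularity, community detection, global efficiency, threshold averaging

two_dyads <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  A
}

test_that("modularity reproduces hand-computed values", {
  set.seed(51)
  A <- rand_adj(6, 0.6)
  # single module: sum(a_ij - d_i d_j / s) = s - s = 0
  expect_equal(modularity(A, rep(1L, 6)), 0, tolerance = 1e-12)
  # two disconnected unit dyads, natural partition: Q = 1/2
  expect_equal(modularity(two_dyads(), c(1L, 1L, 2L, 2L)), 0.5)
  # invariance under relabeling
  memb <- c(1L, 2L, 1L, 3L, 2L, 3L)
  expect_equal(modularity(A, memb), modularity(A, c(3L, 1L, 3L, 2L, 1L, 2L)))
  # edgeless network: defined as 0, with a warning
  expect_warning(q0 <- modularity(matrix(0, 3, 3), c(1L, 2L, 3L)),
                 "no edges")
  expect_equal(q0, 0)
})

test_that("community detection separates disconnected dyads", {
  part <- detect_communities(two_dyads())
  expect_equal(part$n_modules, 2)
  expect_equal(part$membership[1], part$membership[2])
  expect_equal(part$membership[3], part$membership[4])
  expect_false(part$membership[1] == part$membership[3])
  expect_equal(part$modularity, 0.5)
  expect_error(detect_communities(matrix(0, 0, 0)), "no nodes")
})

test_that("exact detection attains the brute-force maximum modularity", {
  set.seed(52)
  for (r in 1:12) {
    m <- sample(4:7, 1)
    A <- rand_adj(m, runif(1, 0.3, 0.8))
    if (sum(A) == 0) next
    part <- detect_communities(A)
    expect_equal(part$modularity, oracle_max_modularity(A),
                 tolerance = 1e-9)
    expect_equal(modularity(A, part), part$modularity, tolerance = 1e-12)
  }
})

test_that("multilevel detection is seeded, reproducible, and competitive", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (r in 1:8) {
    A <- rand_adj(15, 0.3)
    if (sum(A) == 0) next
    p1 <- detect_communities(A, method = "multilevel", seed = 7)
    p2 <- detect_communities(A, method = "multilevel", seed = 7)
    expect_identical(p1$membership, p2$membership)
    # must not fall below the igraph multilevel heuristic by more than a
    # heuristic-vs-heuristic margin
    g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                             weighted = TRUE)
    qig <- igraph::modularity(igraph::cluster_louvain(g))
    expect_gte(p1$modularity, qig - 0.02)
  }
})

test_that("modularity for a given partition matches igraph", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (r in 1:10) {
    m <- sample(5:12, 1)
    A <- rand_adj(m, 0.5)
    if (sum(A) == 0) next
    memb <- sample.int(3, m, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                             weighted = TRUE)
    expect_equal(modularity(A, memb),
                 igraph::modularity(g, memb,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency reproduces hand-computed values", {
  # complete graph, unit weights: every l_ij = 1 -> E = 1
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(global_efficiency(K5), 1)
  # no edges -> all pairs disconnected -> E = 0
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  # 3-node path with unit weights: l = (1, 1, 2) -> E = 5/6
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("both length rules match the Floyd-Warshall oracle", {
  set.seed(55)
  for (r in 1:15) {
    m <- sample(4:12, 1)
    A <- rand_adj(m, runif(1, 0.2, 0.9))
    expect_equal(global_efficiency(A, "weight"),
                 oracle_global_efficiency(A, "weight"), tolerance = 1e-12)
    expect_equal(global_efficiency(A, "inverse"),
                 oracle_global_efficiency(A, "inverse"), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases weight-as-length efficiency", {
  set.seed(56)
  for (r in 1:10) {
    A <- rand_adj(7, 0.4)
    E0 <- global_efficiency(A, "weight")
    zero <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample.int(nrow(zero), 1), ]
    A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- runif(1, 0.1, 1)
    expect_gte(global_efficiency(A, "weight"), E0 - 1e-12)
  }
})

test_that("threshold averaging is the arithmetic mean with strict checks", {
  grid <- default_thresholds()
  expect_equal(average_over_thresholds(rep(0.3, 7), grid), 0.3)
  expect_equal(average_over_thresholds(seq(0.1, 0.7, 0.1), grid), 0.4)
  # order-invariant once values are keyed by threshold
  v <- seq(0.1, 0.7, 0.1)
  names(v) <- format(grid)
  expect_equal(average_over_thresholds(rev(v), grid), 0.4)
  expect_error(average_over_thresholds(v[-3], grid), "0.7")
  v_nan <- v
  v_nan[7] <- NaN
  expect_error(average_over_thresholds(v_nan, grid), "non-finite")
})
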