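star4 <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1
  A
}

path3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  A
}

test_that("thresholding removes connections below tau, negatives included", {
  m <- matrix(0.2, 4, 4); diag(m) <- 1
  tg <- threshold_state(m)
  expect_equal(tg$sparsity, 0)
  expect_true(all(tg$adjacency == 0))
  m2 <- matrix(0.5, 4, 4); diag(m2) <- 1
  tg2 <- threshold_state(m2)
  expect_equal(tg2$sparsity, 1)
  expect_equal(diag(tg2$adjacency), rep(0, 4))
  m3 <- matrix(0, 4, 4)
  m3[1, 2] <- 0.5; m3[1, 3] <- 0.29; m3[2, 3] <- -0.2; m3[3, 4] <- 0.31
  m3 <- m3 + t(m3)
  tg3 <- threshold_state(m3, mode = "weighted")
  expect_equal(sort(tg3$weights[upper.tri(tg3$weights)][tg3$weights[upper.tri(tg3$weights)] != 0]),
               c(0.31, 0.5))
  expect_equal(tg3$sparsity, 2 / 6)
})

test_that("degree counts neighbours or sums weights", {
  tg <- threshold_state(star4() * 0.5)
  expect_equal(graph_degree(tg), c(3, 1, 1, 1))
  expect_equal(graph_degree(tg, weighted = TRUE), c(1.5, 0.5, 0.5, 0.5))
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- 0.4; tri[1, 3] <- 0.5; tri[2, 3] <- 0.6
  tri <- tri + t(tri)
  expect_equal(graph_degree(threshold_state(tri), weighted = TRUE),
               c(0.9, 1.0, 1.1))
  empty <- threshold_state(matrix(0, 4, 4))
  expect_equal(graph_degree(empty), rep(0, 4))
})

test_that("clustering coefficient matches triangle structure", {
  K3 <- 1 - diag(3)
  cc <- clustering_coefficient(K3)
  expect_equal(cc$per_node, rep(1, 3))
  expect_equal(cc$mean, 1)
  expect_equal(clustering_coefficient(path3())$per_node, rep(0, 3))
})

test_that("shortest paths, path length and efficiency on canonical graphs", {
  D3 <- shortest_path_lengths(path3())
  expect_equal(D3[1, 3], 2)
  expect_equal(diag(D3), rep(0, 3), ignore_attr = TRUE)
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1
  D4 <- shortest_path_lengths(two_edges)
  expect_true(all(is.infinite(D4[1:2, 3:4])))
  expect_equal(characteristic_path_length(shortest_path_lengths(1 - diag(3)))$value, 1)
  cpl3 <- characteristic_path_length(D3)
  expect_equal(cpl3$value, 4 / 3)  # hand enumeration: (1.5 + 1 + 1.5) / 3
  expect_equal(cpl3$n_unreachable_pairs, 0)
  cpl4 <- characteristic_path_length(D4)
  expect_equal(cpl4$value, 1)
  expect_equal(cpl4$n_unreachable_pairs, 8)
  none <- characteristic_path_length(shortest_path_lengths(matrix(0, 3, 3)))
  expect_true(is.na(none$value))
  expect_equal(global_efficiency(shortest_path_lengths(1 - diag(5))), 1)
  expect_equal(global_efficiency(shortest_path_lengths(matrix(0, 4, 4))), 0)
  expect_equal(global_efficiency(D3), 5 / 6)
})

test_that("local efficiency on complete and star graphs", {
  K4 <- 1 - diag(4)
  expect_equal(local_efficiency(K4)$per_node, rep(1, 4))
  expect_equal(local_efficiency(star4())$per_node, rep(0, 4))
})

test_that("binary metrics match brute-force oracles on random graphs", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    A <- random_binary_graph(n, runif(1, 0.2, 0.7))
    expect_identical(graph_degree(A), oracle_degree(A))
    expect_equal(clustering_coefficient(A)$per_node, oracle_clustering(A),
                 tolerance = 1e-12)
    D <- shortest_path_lengths(A)
    expect_equal(unname(D), oracle_floyd_warshall(A))
    expect_equal(global_efficiency(D), oracle_global_efficiency(D),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A)$per_node, oracle_local_efficiency(A),
                 tolerance = 1e-12)
    part <- sample(1:3, n, replace = TRUE)
    expect_equal(participation_coefficient(A, part),
                 oracle_participation(A, part), tolerance = 1e-12)
    expect_equal(within_module_zscore(A, part),
                 oracle_within_module_z(A, part), tolerance = 1e-12)
  }
})

test_that("module detection splits two cliques and scores them", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  mod <- detect_modules(A, seed = 3)
  expect_equal(length(unique(mod$partition)), 2)
  expect_equal(length(unique(mod$partition[1:4])), 1)
  expect_equal(length(unique(mod$partition[5:8])), 1)
  expect_gt(mod$modularity, 0.3)
  # no community structure in a complete graph
  expect_lt(detect_modules(1 - diag(6), seed = 1)$modularity, 0.05)
  # empty graph: singleton modules, Q = 0
  e <- detect_modules(matrix(0, 5, 5), seed = 1)
  expect_equal(e$partition, 1:5)
  expect_equal(e$modularity, 0)
})

test_that("participation and within-module z-score on hand-built cases", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- 1   # node 1 inside module 1
  A[4, 5] <- A[5, 4] <- 1
  A[3, 4] <- A[4, 3] <- 1                          # node 3/4 bridge
  part <- c(1, 1, 1, 2, 2, 2)
  pc <- participation_coefficient(A, part)
  expect_equal(pc[1], 0)                        # all edges intramodule
  expect_equal(pc[3], 0.5)                      # degree 2 split over 2 modules
  expect_equal(pc[6], 0)                        # isolated node
  # within-degrees (2, 1, 1) in a 3-node module, population sd
  B <- matrix(0, 3, 3)
  B[1, 2] <- B[2, 1] <- B[1, 3] <- B[3, 1] <- 1
  z <- within_module_zscore(B, rep(1, 3))
  expect_equal(z, c(sqrt(2), -1 / sqrt(2), -1 / sqrt(2)))
  # regular graph in one module: all z zero; singleton module: zero
  expect_equal(within_module_zscore(1 - diag(4), rep(1, 4)), rep(0, 4))
  expect_equal(within_module_zscore(matrix(0, 1, 1), 1), 0)
})

test_that("adding an edge cannot lengthen paths or reduce efficiency", {
  set.seed(21)
  for (i in 1:15) {
    A <- random_binary_graph(7, 0.3)
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    DA <- shortest_path_lengths(A); DB <- shortest_path_lengths(B)
    la <- characteristic_path_length(DA)$value
    lb <- characteristic_path_length(DB)$value
    if (!is.na(la) && !is.na(lb) &&
        characteristic_path_length(DA)$n_unreachable_pairs ==
        characteristic_path_length(DB)$n_unreachable_pairs) {
      expect_lte(lb, la + 1e-12)
    }
    expect_gte(global_efficiency(DB), global_efficiency(DA) - 1e-12)
  }
})

test_that("node relabeling permutes node metrics and fixes global ones", {
  set.seed(22)
  A <- random_binary_graph(7, 0.5)
  perm <- sample(7)
  B <- A[perm, perm]
  expect_equal(graph_degree(B), graph_degree(A)[perm])
  expect_equal(clustering_coefficient(B)$mean, clustering_coefficient(A)$mean)
  expect_equal(global_efficiency(shortest_path_lengths(B)),
               global_efficiency(shortest_path_lengths(A)))
  expect_equal(characteristic_path_length(shortest_path_lengths(B))$value,
               characteristic_path_length(shortest_path_lengths(A))$value)
})

test_that("state-set graph metrics assemble tidy tables", {
  set.seed(23)
  states <- lapply(c(0.6, 0.35), function(mu) {
    m <- matrix(mu, 10, 10) + matrix(rnorm(100, sd = 0.05), 10)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  gm <- state_graph_metrics(states, tau = 0.3, seed = 4)
  expect_equal(nrow(gm$node_metrics), 20)
  expect_equal(nrow(gm$global_metrics), 2)
  expect_true(all(gm$node_metrics$clustering >= 0 &
                    gm$node_metrics$clustering <= 1))
  expect_true(all(gm$node_metrics$participation >= 0 &
                    gm$node_metrics$participation <= 1))
  expect_true(all(gm$global_metrics$global_efficiency >= 0 &
                    gm$global_metrics$global_efficiency <= 1))
  # denser high-mean state: more edges, shorter paths
  expect_gt(gm$global_metrics$sparsity[1], gm$global_metrics$sparsity[2])
})
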