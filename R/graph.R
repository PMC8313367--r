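#' Threshold a state connectivity matrix into a graph
#'
#' Connections with value strictly lower than `tau` are regarded as
#' disconnected and set to 0 (negative connections are therefore removed
#' as well). In binary mode surviving edges become 1. The threshold is
#' applied to the Fisher-Z state centroid values; the default 0.3 follows
#' the convention that weaker connections are treated as absent.
#'
#' @param state_matrix symmetric M x M matrix (e.g. one state from a
#'   `state_set`).
#' @param tau disconnection threshold (default 0.3).
#' @param mode `"binary"` (default; metrics below assume it) or
#'   `"weighted"`.
#' @return a `thresholded_graph`: `adjacency`, `weights` (suprathreshold
#'   values), `mode`, `tau`, `sparsity` (present edges over `M(M-1)/2`).
#' @export
threshold_state <- function(state_matrix, tau = 0.3,
                            mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  A <- as.matrix(state_matrix)
  assert_that(isTRUE(all.equal(A, t(A), tolerance = 1e-8)),
              "state matrix must be symmetric")
  A <- (A + t(A)) / 2
  diag(A) <- 0
  W <- ifelse(A < tau, 0, A)
  M <- nrow(A)
  sparsity <- sum(W[upper.tri(W)] != 0) / (M * (M - 1) / 2)
  adjacency <- if (mode == "binary") (W != 0) * 1 else W
  structure(list(adjacency = adjacency, weights = W, mode = mode,
                 tau = tau, sparsity = sparsity,
                 region_labels = colnames(A) %||% paste0("R", seq_len(M))),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %s mode, tau = %g, sparsity %.3f\n",
              nrow(x$adjacency), x$mode, x$tau, x$sparsity))
  invisible(x)
}

as_adjacency <- function(graph) {
  if (inherits(graph, "thresholded_graph")) graph$adjacency else as.matrix(graph)
}

binary_adjacency <- function(graph) {
  A <- as_adjacency(graph)
  (A != 0) * 1
}

#' Node degree
#'
#' Binary mode: the number of suprathreshold neighbours. Weighted mode:
#' the sum of suprathreshold connection weights (the definition used to
#' rank hub regions).
#'
#' @param graph a `thresholded_graph` or adjacency matrix.
#' @param weighted sum weights instead of counting neighbours.
#' @return per-node numeric vector.
#' @export
graph_degree <- function(graph, weighted = FALSE) {
  A <- if (weighted) {
    if (inherits(graph, "thresholded_graph")) graph$weights else as.matrix(graph)
  } else {
    binary_adjacency(graph)
  }
  rowSums(A)
}

#' Clustering coefficient (binary)
#'
#' `CC_i = 2 t_i / (k_i (k_i - 1))` where `t_i` counts triangles through
#' node `i`; nodes with degree below 2 get 0. A segregation measure.
#'
#' @param graph a `thresholded_graph` or adjacency matrix (binarized).
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  A <- binary_adjacency(graph)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  list(per_node = cc, mean = mean(cc))
}

#' Shortest-path hop counts between all node pairs
#'
#' Breadth-first distances on the binarized graph; unreachable pairs are
#' `Inf`, the diagonal 0.
#'
#' @param graph a `thresholded_graph` or adjacency matrix.
#' @return M x M distance matrix.
#' @export
shortest_path_lengths <- function(graph) {
  A <- binary_adjacency(graph)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  dimnames(D) <- dimnames(A)
  D
}

#' Characteristic path length
#'
#' Mean over nodes of each node's mean distance to the others, an
#' integration measure. Unreachable pairs are excluded from the averages
#' (their count is reported); a node reaching no one is excluded from the
#' outer mean.
#'
#' @param distances matrix from [shortest_path_lengths()].
#' @return list with `value` (NA when no finite off-diagonal distance
#'   exists), `n_unreachable_pairs` (ordered pairs excluded) and
#'   `n_isolated_nodes`.
#' @export
characteristic_path_length <- function(distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  diag(D) <- NA
  reachable <- is.finite(D)
  n_unreachable <- sum(!reachable & !is.na(D))
  Li <- vapply(seq_len(n), function(i) {
    di <- D[i, ][reachable[i, ]]
    if (length(di) == 0) NA_real_ else mean(di)
  }, 0)
  value <- if (all(is.na(Li))) NA_real_ else mean(Li, na.rm = TRUE)
  list(value = value, n_unreachable_pairs = n_unreachable,
       n_isolated_nodes = sum(is.na(Li)))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' `1/Inf = 0`, so the measure remains meaningful on disconnected graphs.
#'
#' @param distances matrix from [shortest_path_lengths()].
#' @return scalar in `[0, 1]` for binary graphs.
#' @export
global_efficiency <- function(distances) {
  D <- as.matrix(distances)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(D)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency (binary)
#'
#' For each node, the mean inverse shortest-path distance between its
#' neighbours computed within the subgraph induced by those neighbours;
#' 0 for degree below 2. Captures fault tolerance of local information
#' transfer.
#'
#' @param graph a `thresholded_graph` or adjacency matrix.
#' @return list with `per_node` and `mean`.
#' @export
local_efficiency <- function(graph) {
  A <- binary_adjacency(graph)
  n <- nrow(A)
  k <- rowSums(A)
  per <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] != 0)
    Dn <- shortest_path_lengths(A[nb, nb, drop = FALSE])
    inv <- 1 / Dn
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    per[i] <- sum(inv) / (k[i] * (k[i] - 1))
  }
  list(per_node = per, mean = mean(per))
}

#' Greedy modularity community detection
#'
#' Louvain-style multilevel modularity maximization with several seeded
#' restarts, keeping the best-Q partition. The algorithm behind the
#' modularity indicator is a free choice; the multilevel heuristic is the
#' standard one for brain networks.
#'
#' @param graph a `thresholded_graph` or adjacency matrix (weights used
#'   when present).
#' @param seed integer seed (restarts derive from it).
#' @param n_restarts number of restarts (default 10).
#' @return list with `partition` (integer module id per node) and
#'   `modularity` (Q of the returned partition).
#' @export
detect_modules <- function(graph, seed = 1, n_restarts = 10) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (all(A == 0)) {
    return(list(partition = seq_len(n), modularity = 0))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(split_seed(seed, 41, r))
    cl <- igraph::cluster_louvain(g)
    q <- igraph::modularity(cl)
    if (is.null(best) || q > best$modularity) {
      best <- list(partition = as.integer(igraph::membership(cl)),
                   modularity = q)
    }
  }
  best
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` is node `i`'s degree
#' into module `m`. High values mark connector hubs that promote global
#' integration; isolated nodes get 0.
#'
#' @param graph a `thresholded_graph` or adjacency matrix.
#' @param partition integer module id per node.
#' @param weighted use weighted degrees.
#' @return per-node numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(graph, partition, weighted = FALSE) {
  A <- if (weighted && inherits(graph, "thresholded_graph")) graph$weights
       else binary_adjacency(graph)
  k <- rowSums(A)
  mods <- sort(unique(partition))
  km <- vapply(mods, function(m) rowSums(A[, partition == m, drop = FALSE]), k)
  p <- 1 - rowSums((km / ifelse(k == 0, 1, k))^2)
  ifelse(k == 0, 0, p)
}

#' Within-module degree z-score
#'
#' Standardizes each node's within-module degree against the mean and
#' population standard deviation of within-module degrees in its own
#' module. High values mark provincial hubs; modules with zero spread
#' give z = 0.
#'
#' @param graph a `thresholded_graph` or adjacency matrix.
#' @param partition integer module id per node.
#' @param weighted use weighted degrees.
#' @return per-node numeric vector.
#' @export
within_module_zscore <- function(graph, partition, weighted = FALSE) {
  A <- if (weighted && inherits(graph, "thresholded_graph")) graph$weights
       else binary_adjacency(graph)
  n <- nrow(A)
  kappa <- vapply(seq_len(n), function(i) {
    sum(A[i, partition == partition[i]])
  }, 0)
  z <- numeric(n)
  for (m in unique(partition)) {
    idx <- partition == m
    mu <- mean(kappa[idx])
    sdm <- sqrt(mean((kappa[idx] - mu)^2))  # population sd
    z[idx] <- if (sdm == 0) 0 else (kappa[idx] - mu) / sdm
  }
  z
}

#' Graph indicators for every state of a state set
#'
#' Thresholds each state matrix and computes the full panel of nodal and
#' global integration/segregation indicators.
#'
#' @param state_set a `state_set` (or list of symmetric matrices).
#' @param tau disconnection threshold applied to the Fisher-Z centroid
#'   values (default 0.3).
#' @param mode `"binary"` or `"weighted"` thresholding; nodal binary
#'   metrics are always computed on the binarized graph, weighted degree
#'   is reported alongside.
#' @param seed seed for module detection.
#' @return list of two tibbles: `node_metrics` (state, node, region,
#'   degree, weighted_degree, clustering, local_efficiency, module,
#'   participation, within_module_z) and `global_metrics` (state,
#'   sparsity, char_path_length, n_unreachable_pairs, global_efficiency,
#'   mean_clustering, mean_local_efficiency, modularity, n_modules).
#' @export
state_graph_metrics <- function(state_set, tau = 0.3,
                                mode = c("binary", "weighted"), seed = 1) {
  mode <- match.arg(mode)
  mats <- if (inherits(state_set, "state_set")) state_set$states else state_set
  node_rows <- list()
  global_rows <- list()
  for (s in seq_along(mats)) {
    tg <- threshold_state(mats[[s]], tau = tau, mode = mode)
    deg <- graph_degree(tg)
    wdeg <- graph_degree(tg, weighted = TRUE)
    cc <- clustering_coefficient(tg)
    D <- shortest_path_lengths(tg)
    cpl <- characteristic_path_length(D)
    eg <- global_efficiency(D)
    el <- local_efficiency(tg)
    mod <- detect_modules(tg, seed = split_seed(seed, 51, s))
    pc <- participation_coefficient(tg, mod$partition)
    z <- within_module_zscore(tg, mod$partition)
    M <- nrow(tg$adjacency)
    node_rows[[s]] <- tibble::tibble(
      state = s, node = seq_len(M), region = tg$region_labels,
      degree = deg, weighted_degree = wdeg, clustering = cc$per_node,
      local_efficiency = el$per_node, module = mod$partition,
      participation = pc, within_module_z = z)
    global_rows[[s]] <- tibble::tibble(
      state = s, sparsity = tg$sparsity, char_path_length = cpl$value,
      n_unreachable_pairs = cpl$n_unreachable_pairs,
      global_efficiency = eg, mean_clustering = cc$mean,
      mean_local_efficiency = el$mean, modularity = mod$modularity,
      n_modules = length(unique(mod$partition)))
  }
  list(node_metrics = dplyr::bind_rows(node_rows),
       global_metrics = dplyr::bind_rows(global_rows))
}
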