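#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a state set into one row per state
#'
#' @param x a `state_set`.
#' @param ... unused.
#' @return tibble with `state`, `state_mean`, `occupancy`.
#' @export
tidy.state_set <- function(x, ...) {
  tibble::tibble(state = seq_len(x$k), state_mean = x$state_means,
                 occupancy = x$occupancy)
}

#' One-row summary of a state set
#'
#' @param x a `state_set`.
#' @param ... unused.
#' @return tibble with `k`, `n_windows`, `n_subjects`, `stage1_inertia`,
#'   `stage2_inertia`, `metric`.
#' @export
glance.state_set <- function(x, ...) {
  tibble::tibble(k = x$k, n_windows = nrow(x$assignments),
                 n_subjects = length(unique(x$assignments$subject_id)),
                 stage1_inertia = x$stage1$inertia,
                 stage2_inertia = x$stage2$inertia, metric = x$metric)
}

#' Tidy a k-means fit into one row per cluster
#'
#' @param x a `kmeans_result`.
#' @param ... unused.
#' @return tibble with `cluster`, `size`, `centroid_mean`.
#' @export
tidy.kmeans_result <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k),
                 size = tabulate(x$labels, x$k),
                 centroid_mean = rowMeans(x$centroids))
}

#' One-row summary of a k-means fit
#'
#' @param x a `kmeans_result`.
#' @param ... unused.
#' @export
glance.kmeans_result <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, n_iter = x$n_iter,
                 n_reseeds = x$n_reseeds, metric = x$metric,
                 update = x$update)
}

#' Tidy edge-wise test results into a long edge table
#'
#' @param x an `edge_test`.
#' @param ... unused.
#' @return tibble with `i`, `j`, `region_i`, `region_j`, `t`, `p`,
#'   `fdr_significant` (BH at 5%).
#' @export
tidy.edge_test <- function(x, ...) {
  M <- nrow(x$t_matrix)
  labels <- rownames(x$t_matrix) %||% paste0("R", seq_len(M))
  pairs <- which(upper.tri(x$t_matrix), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                 region_i = labels[pairs[, 1]], region_j = labels[pairs[, 2]],
                 t = x$t, p = x$p, fdr_significant = fdr_bh(x$p, 0.05))
}

#' Tidy NBS results into one row per component
#'
#' @param x an `nbs_result`.
#' @param ... unused.
#' @export
tidy.nbs_result <- function(x, ...) x$components

#' One-row summary of an NBS run
#'
#' @param x an `nbs_result`.
#' @param ... unused.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(primary_threshold = x$primary_threshold,
                 n_permutations = x$n_permutations,
                 n_components = nrow(x$components),
                 min_p = if (nrow(x$components)) min(x$components$p) else NA_real_,
                 largest_component = if (nrow(x$components))
                   max(x$components$n_edges) else 0L)
}

#' One-row summary of a full pipeline report
#'
#' @param x a `dfc_report`.
#' @param ... unused.
#' @return tibble with the chosen `k`, top-two occupancy share, the
#'   smallest dynamics-test p-value and the smallest NBS component p.
#' @export
glance.dfc_report <- function(x, ...) {
  occ <- sort(x$states$occupancy, decreasing = TRUE)
  tibble::tibble(
    k = x$states$k,
    window_seconds = x$config$window_seconds,
    top2_occupancy = sum(occ[seq_len(min(2, length(occ)))]),
    min_dynamics_p = if (!is.null(x$dynamics_tests))
      min(x$dynamics_tests$p) else NA_real_,
    min_nbs_p = if (length(x$nbs))
      min(vapply(x$nbs, function(r)
        if (nrow(r$components)) min(r$components$p) else NA_real_, 0),
        na.rm = TRUE) else NA_real_)
}
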