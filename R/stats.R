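#' Per-subject mean connectivity within one state
#'
#' A subject's edge value for a state is the elementwise mean of that
#' subject's windowed Fisher-Z matrices over the windows assigned to the
#' state. Subjects with no window in the state are excluded (and listed),
#' since they provide no estimate of the state's connectivity.
#'
#' @param cohort list of `windowed_fc` objects.
#' @param assignments assignment tibble (subject_id, group, window_index,
#'   state) or a `state_set`.
#' @param state state of interest.
#' @return list with `features` (subjects x M(M-1)/2 matrix of vectorized
#'   mean FC), `subject_id`, `group`, `excluded` (subject ids with no
#'   window in the state), `region_labels`.
#' @export
subject_state_fc <- function(cohort, assignments, state) {
  if (inherits(assignments, "state_set")) assignments <- assignments$assignments
  ids <- vapply(cohort, function(w) w$subject_id, "")
  rows <- list()
  keep_id <- character(0)
  keep_group <- character(0)
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    asn <- assignments[assignments$subject_id == ids[i], ]
    win <- asn$window_index[asn$state == state]
    if (length(win) == 0) {
      excluded <- c(excluded, ids[i])
      next
    }
    feats <- window_feature_matrix(cohort[[i]])
    rows[[length(rows) + 1]] <- colMeans(feats[win, , drop = FALSE])
    keep_id <- c(keep_id, ids[i])
    keep_group <- c(keep_group, cohort[[i]]$group)
  }
  list(features = do.call(rbind, rows), subject_id = keep_id,
       group = keep_group, excluded = excluded,
       region_labels = cohort[[1]]$region_labels)
}

# Pooled-variance two-sample t for every column of two stacks; returns
# list(t, df). Zero-variance columns with equal means give t = 0.
column_t <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(a^2) - na * ma^2
  vb <- colSums(b^2) - nb * mb^2
  sp2 <- (va + vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0 & abs(ma - mb) < 1e-12] <- 0
  t[se == 0 & abs(ma - mb) >= 1e-12] <- Inf * sign(ma - mb)[se == 0 & abs(ma - mb) >= 1e-12]
  list(t = t, df = na + nb - 2)
}

#' Edge-wise two-sample t-test between groups
#'
#' Independent pooled-variance t per connectivity edge on two stacks of
#' per-subject vectorized FC (e.g. from [subject_state_fc()]).
#'
#' @param stack_a,stack_b subjects x edges matrices.
#' @param region_labels optional region names for the matrix forms.
#' @return an `edge_test`: `t_matrix`, `p_matrix` (symmetric, zero/one on
#'   the diagonal), `t`, `p` (edge vectors), `df`, `n_a`, `n_b`.
#' @export
edgewise_t <- function(stack_a, stack_b, region_labels = NULL) {
  a <- as.matrix(stack_a); b <- as.matrix(stack_b)
  assert_that(nrow(a) >= 2 && nrow(b) >= 2,
              "each group needs at least two subjects")
  assert_that(ncol(a) == ncol(b), "stacks must cover the same edges")
  ct <- column_t(a, b)
  p <- 2 * pt(-abs(ct$t), ct$df)
  p[!is.finite(ct$t)] <- 0
  tm <- devectorize_upper(ct$t)
  pm <- devectorize_upper(p, diag_value = 1)
  if (!is.null(region_labels)) {
    dimnames(tm) <- dimnames(pm) <- list(region_labels, region_labels)
  }
  structure(list(t_matrix = tm, p_matrix = pm, t = ct$t, p = p,
                 df = ct$df, n_a = nrow(a), n_b = nrow(b)),
            class = "edge_test")
}

#' Benjamini-Hochberg FDR mask
#'
#' @param p_values vector of p-values.
#' @param q FDR level (default 0.05).
#' @return logical vector: TRUE where the edge survives the step-up rule.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= q
}

suprathreshold_components <- function(t_vec, threshold, M) {
  mask <- abs(t_vec) >= threshold
  if (!any(mask)) {
    return(list(sizes = integer(0), membership = rep(NA_integer_,
                                                     length(t_vec))))
  }
  A <- devectorize_upper(as.numeric(mask))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  edge_idx <- which(mask)
  pairs <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  # vectorize_upper is row-major; rebuild the same ordering
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  membership <- rep(NA_integer_, length(t_vec))
  membership[edge_idx] <- comp$membership[pairs[edge_idx, 1]]
  sizes <- as.integer(table(membership[edge_idx]))
  comp_ids <- as.integer(names(table(membership[edge_idx])))
  # renumber components by decreasing edge count
  ord2 <- order(-sizes)
  remap <- setNames(seq_along(comp_ids), comp_ids[ord2])
  membership[edge_idx] <- remap[as.character(membership[edge_idx])]
  list(sizes = sizes[ord2], membership = membership)
}

#' Network-based statistic permutation test
#'
#' Forms the graph of edges whose |t| exceeds a primary threshold,
#' identifies its connected components, and assesses each observed
#' component's edge count against the null distribution of the maximal
#' component size obtained by fully permuting subjects' group labels.
#' Family-wise error over components is thereby controlled.
#'
#' @param stack_a,stack_b subjects x edges matrices of per-subject FC.
#' @param primary_threshold component-forming |t| cutoff (default 3.0, in
#'   the range of typical significant edge statistics).
#' @param n_permutations number of label permutations (>= 100; default
#'   5000).
#' @param seed integer seed.
#' @param region_labels optional region names.
#' @return an `nbs_result`: `components` (tibble: component, n_edges,
#'   p), `edge_table` (tibble: i, j, region_i, region_j, t, component),
#'   `null_max_sizes`, `primary_threshold`, `n_permutations`, `seed`.
#' @export
nbs <- function(stack_a, stack_b, primary_threshold = 3,
                n_permutations = 5000, seed = 1, region_labels = NULL) {
  assert_that(n_permutations >= 100, "need at least 100 permutations")
  a <- as.matrix(stack_a); b <- as.matrix(stack_b)
  na <- nrow(a); nb <- nrow(b)
  E <- ncol(a)
  M <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  obs <- column_t(a, b)
  oc <- suprathreshold_components(obs$t, primary_threshold, M)
  x <- rbind(a, b)
  set.seed(seed)
  null_max <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    idx <- sample.int(na + nb, na)
    pt_ <- column_t(x[idx, , drop = FALSE], x[-idx, , drop = FALSE])
    pc <- suprathreshold_components(pt_$t, primary_threshold, M)
    null_max[p] <- if (length(pc$sizes)) max(pc$sizes) else 0L
  }
  comp_p <- vapply(oc$sizes, function(sz) {
    (1 + sum(null_max >= sz)) / (n_permutations + 1)
  }, 0)
  labels <- region_labels %||% paste0("R", seq_len(M))
  pairs <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  edge_idx <- which(!is.na(oc$membership))
  edge_table <- tibble::tibble(
    i = pairs[edge_idx, 1], j = pairs[edge_idx, 2],
    region_i = labels[pairs[edge_idx, 1]],
    region_j = labels[pairs[edge_idx, 2]],
    t = obs$t[edge_idx], component = oc$membership[edge_idx])
  structure(list(
    components = tibble::tibble(component = seq_along(oc$sizes),
                                n_edges = oc$sizes, p = comp_p),
    edge_table = edge_table, null_max_sizes = null_max,
    primary_threshold = primary_threshold,
    n_permutations = n_permutations, seed = seed,
    t = obs$t, df = obs$df),
    class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> |t| >= %g, %d permutations\n",
              x$primary_threshold, x$n_permutations))
  if (nrow(x$components) == 0) {
    cat("  no suprathreshold edges\n")
  } else {
    print(x$components)
  }
  invisible(x)
}
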