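#' Manhattan (L1) distance between two vectors
#'
#' The similarity measure used for state clustering: in the
#' high-dimensional space of vectorized connectivity matrices the L1
#' distance discriminates more effectively than L2.
#'
#' @param a,b numeric vectors of equal length.
#' @return scalar distance.
#' @export
#' @examples
#' manhattan_distance(c(0, 0), c(1, 2))
manhattan_distance <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  sum(abs(a - b))
}

cross_distance <- function(x, centers, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  .cross_distance_cpp(x, centers, if (metric == "manhattan") 1L else 2L)
}

#' k-means++ seeding
#'
#' First center uniform over the samples; each further center is drawn with
#' probability proportional to the squared distance (under the configured
#' metric) to the nearest already-chosen center.
#'
#' @param samples n x d matrix, one sample per row.
#' @param k number of centers (`k <= n`).
#' @param seed integer seed.
#' @param metric `"manhattan"` or `"euclidean"`.
#' @return k x d matrix of initial centers.
#' @export
kmeans_pp_init <- function(samples, k, seed,
                           metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  samples <- as.matrix(samples)
  n <- nrow(samples)
  assert_that(k >= 1 && k <= n, "k must be between 1 and the number of samples")
  set.seed(seed)
  chosen <- integer(k)
  chosen[1] <- sample.int(n, 1)
  if (k > 1) {
    dmin <- cross_distance(samples, samples[chosen[1], , drop = FALSE],
                           metric)[, 1]
    for (j in 2:k) {
      w <- dmin^2
      if (sum(w) <= 0) {
        # all remaining mass at already-chosen points: fall back to uniform
        cand <- setdiff(seq_len(n), chosen[seq_len(j - 1)])
        chosen[j] <- cand[sample.int(length(cand), 1)]
      } else {
        chosen[j] <- sample.int(n, 1, prob = w)
      }
      dj <- cross_distance(samples, samples[chosen[j], , drop = FALSE],
                           metric)[, 1]
      dmin <- pmin(dmin, dj)
    }
  }
  samples[chosen, , drop = FALSE]
}

centroid_update <- function(x, labels, k, update) {
  if (update == "mean") {
    C <- .group_colmeans_cpp(x, labels, k)
  } else {
    C <- .group_colmedians_cpp(x, labels, k)
  }
  C
}

#' k-means clustering with Manhattan or Euclidean distance
#'
#' Lloyd-style alternation: assign every sample to its nearest centroid
#' under `metric` (ties to the lowest centroid index), then recompute each
#' centroid from its members. With the Manhattan metric the default update
#' is the coordinate-wise median (k-medians), which makes the recorded
#' objective provably non-increasing; the coordinate-wise mean is available
#' via `update = "mean"`. Empty clusters are repaired by re-seeding the
#' centroid at the sample farthest from its current assignment, which also
#' preserves monotonicity of the objective.
#'
#' @param samples n x d numeric matrix.
#' @param k number of clusters.
#' @param init_centroids optional k x d matrix of starting centers; when
#'   given, a single run starts there (no restarts).
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @param update centroid update rule: `"median"` (default for manhattan)
#'   or `"mean"` (default for euclidean).
#' @param max_iter iteration cap per run.
#' @param n_restarts independent k-means++ restarts; the run with minimal
#'   inertia is returned.
#' @param seed integer seed.
#' @return a `kmeans_result`: `centroids`, `labels`, `inertia` (sum of
#'   distances to assigned centroids under `metric`), `n_iter`,
#'   `inertia_trace` (one value per iteration of the winning run),
#'   `n_reseeds`, plus the configuration.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' fit <- l1_kmeans(x, 2, seed = 1, n_restarts = 5)
#' fit$inertia
l1_kmeans <- function(samples, k, init_centroids = NULL,
                      metric = c("manhattan", "euclidean"), update = NULL,
                      max_iter = 100, n_restarts = 1, seed = 1) {
  metric <- match.arg(metric)
  update <- update %||% if (metric == "manhattan") "median" else "mean"
  assert_that(update %in% c("median", "mean"), "unknown update rule")
  x <- as.matrix(samples)
  n <- nrow(x)
  assert_that(k >= 1 && n >= k, "need at least k samples")

  run_once <- function(C) {
    labels_prev <- integer(0)
    trace <- numeric(0)
    n_reseeds <- 0L
    labels <- integer(n)
    for (it in seq_len(max_iter)) {
      D <- cross_distance(x, C, metric)
      labels <- max.col(-D, ties.method = "first")
      empty <- which(tabulate(labels, k) == 0L)
      while (length(empty) > 0) {
        far <- which.max(D[cbind(seq_len(n), labels)])
        C[empty[1], ] <- x[far, ]
        n_reseeds <- n_reseeds + 1L
        D <- cross_distance(x, C, metric)
        labels <- max.col(-D, ties.method = "first")
        empty <- which(tabulate(labels, k) == 0L)
      }
      trace <- c(trace, sum(D[cbind(seq_len(n), labels)]))
      if (identical(labels, labels_prev)) break
      labels_prev <- labels
      C <- centroid_update(x, labels, k, update)
    }
    inertia <- sum(cross_distance(x, C, metric)[cbind(seq_len(n), labels)])
    list(centroids = C, labels = labels, inertia = inertia,
         n_iter = length(trace), inertia_trace = trace,
         n_reseeds = n_reseeds)
  }

  if (!is.null(init_centroids)) {
    best <- run_once(as.matrix(init_centroids))
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      C0 <- kmeans_pp_init(x, k, seed = split_seed(seed, 7, r),
                           metric = metric)
      fit <- run_once(C0)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  }
  structure(c(best, list(metric = metric, update = update, k = k,
                         seed = seed)),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("<kmeans_result> k = %d, %s metric (%s update), inertia %.4g after %d iterations\n",
              x$k, x$metric, x$update, x$inertia, x$n_iter))
  invisible(x)
}

#' Select a subject's highest-variance windows as clustering exemplars
#'
#' Ranks a subject's windows by the population variance of their
#' vectorized Fisher-Z connectivity entries and keeps the top
#' `n_exemplars` (ties broken by earlier window index). These exemplars
#' feed the first clustering stage; using a handful of high-variance
#' windows per subject reduces redundancy and computation.
#'
#' @param wfc a `windowed_fc`.
#' @param n_exemplars number of windows to keep (default 7, within the
#'   customary 6-8 range).
#' @return list with `features` (n_exemplars x M(M-1)/2 matrix),
#'   `window_index` (1-based indices of the chosen windows) and
#'   `variance` (their ranking statistic).
#' @export
select_exemplars <- function(wfc, n_exemplars = 7) {
  feats <- window_feature_matrix(wfc)
  N <- nrow(feats)
  assert_that(n_exemplars >= 1 && n_exemplars <= N,
              "n_exemplars must be between 1 and the number of windows")
  v <- apply(feats, 1, window_variance)
  ord <- order(-v, seq_len(N))
  keep <- ord[seq_len(n_exemplars)]
  list(features = feats[keep, , drop = FALSE], window_index = keep,
       variance = v[keep])
}

#' Select the number of states from the intra/inter distance ratio
#'
#' For each candidate `k` the samples are clustered and the clustering
#' effectiveness index is recorded: the mean over samples of the ratio of
#' the sample's intra-cluster distance (its mean distance to the other
#' members of its cluster) to its inter-cluster distance (its mean
#' distance to the members of the nearest other cluster). The index falls
#' while added clusters separate genuine structure and rises once they
#' start splitting homogeneous clusters, so the chosen `k` is the curve's
#' minimum — the bend at which further clusters stop helping. The full
#' curve is returned so the choice can be overridden manually.
#'
#' @param samples n x d matrix.
#' @param k_range candidate cluster numbers (default `2:10`).
#' @param metric distance metric, as in [l1_kmeans()].
#' @param seed integer seed.
#' @param n_restarts restarts per candidate `k`.
#' @return an `elbow_curve`: tibble with columns `k`, `ratio` (the
#'   effectiveness index), `within_mean` and `between_mean` (its pooled
#'   components), plus attribute `chosen_k`.
#' @export
elbow_select_k <- function(samples, k_range = 2:10,
                           metric = c("manhattan", "euclidean"), seed = 1,
                           n_restarts = 10) {
  metric <- match.arg(metric)
  x <- as.matrix(samples)
  n <- nrow(x)
  assert_that(min(k_range) >= 2 && max(k_range) <= n - 1,
              "k_range must lie within [2, n_samples - 1]")
  if (all(cross_distance(x, x[1, , drop = FALSE], metric) == 0)) {
    stop("all samples identical: cluster number is undefined", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  Dp <- cross_distance(x, x, metric)
  ut <- upper.tri(Dp)
  fits <- lapply(k_range, function(k) {
    l1_kmeans(x, k, metric = metric, n_restarts = n_restarts,
              seed = split_seed(seed, 11, k))
  })
  ratio <- vapply(fits, function(f) intra_inter_ratio(Dp, f$labels, f$k), 0)
  within_mean <- vapply(fits, function(f) {
    same <- outer(f$labels, f$labels, `==`)
    mean(Dp[same & ut])
  }, 0)
  between_mean <- vapply(fits, function(f) {
    same <- outer(f$labels, f$labels, `==`)
    mean(Dp[!same & ut])
  }, 0)
  chosen <- k_range[which.min(ratio)]
  out <- tibble::tibble(k = k_range, ratio = ratio,
                        within_mean = within_mean,
                        between_mean = between_mean)
  structure(out, chosen_k = chosen,
            class = c("elbow_curve", class(out)))
}

# Mean over samples of (mean distance to own cluster) / (mean distance to
# the nearest other cluster); singleton clusters contribute ratio 0.
intra_inter_ratio <- function(Dp, labels, k) {
  n <- nrow(Dp)
  idx_by <- split(seq_len(n), factor(labels, levels = seq_len(k)))
  r <- numeric(n)
  for (c in seq_len(k)) {
    idx <- idx_by[[c]]
    if (length(idx) == 0) next
    a <- if (length(idx) == 1) 0 else
      rowSums(Dp[idx, idx, drop = FALSE]) / (length(idx) - 1)
    b <- rep(Inf, length(idx))
    for (o in seq_len(k)) {
      if (o == c || length(idx_by[[o]]) == 0) next
      b <- pmin(b, rowMeans(Dp[idx, idx_by[[o]], drop = FALSE]))
    }
    r[idx] <- ifelse(is.finite(b) & b > 0, a / b, 0)
  }
  mean(r)
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("<elbow_curve> chosen k = %d\n", attr(x, "chosen_k")))
  NextMethod()
}

state_order_by_mean <- function(centroids) {
  means <- rowMeans(centroids)
  order(-means, seq_len(nrow(centroids)))
}

#' Two-stage extraction of functional connectivity states
#'
#' Stage 1 pools every subject's high-variance exemplar windows and
#' clusters them with multiple k-means++ restarts; the resulting centroids
#' seed stage 2, a single k-means run to convergence over *all* windows of
#' all subjects. States are then ordered by descending centroid mean and
#' window assignments relabeled accordingly.
#'
#' @param cohort list of `windowed_fc` objects, one per subject.
#' @param k number of states; use [elbow_select_k()] on the pooled
#'   exemplars to choose it.
#' @param n_exemplars exemplar windows per subject (default 7).
#' @param metric distance metric (default Manhattan).
#' @param seed integer seed.
#' @param n_restarts stage-1 restarts (default 50).
#' @param update centroid update rule, see [l1_kmeans()].
#' @return a `state_set`: list with `states` (list of K symmetric M x M
#'   Fisher-Z matrices), `centroids` (K x M(M-1)/2), `state_means`,
#'   `occupancy`, `assignments` (tibble: subject_id, group, window_index,
#'   state), `k`, `stage1`, `stage2` fit summaries, `region_labels`.
#' @export
two_stage_cluster <- function(cohort, k, n_exemplars = 7,
                              metric = c("manhattan", "euclidean"),
                              seed = 1, n_restarts = 50, update = NULL) {
  metric <- match.arg(metric)
  assert_that(length(cohort) >= 1, "cohort must be nonempty")
  exemplars <- do.call(rbind, lapply(cohort, function(w) {
    select_exemplars(w, min(n_exemplars, length(w$matrices)))$features
  }))
  stage1 <- l1_kmeans(exemplars, k, metric = metric, update = update,
                      n_restarts = n_restarts, seed = split_seed(seed, 21))
  all_feats <- do.call(rbind, lapply(cohort, window_feature_matrix))
  n_windows <- vapply(cohort, function(w) length(w$matrices), 1L)
  stage2 <- l1_kmeans(all_feats, k, init_centroids = stage1$centroids,
                      metric = metric, update = update,
                      seed = split_seed(seed, 22))
  ord <- state_order_by_mean(stage2$centroids)
  relabel <- match(seq_len(k), ord)  # old label -> new rank
  centroids <- stage2$centroids[ord, , drop = FALSE]
  labels <- relabel[stage2$labels]
  occupancy <- tabulate(labels, k) / length(labels)
  assignments <- tibble::tibble(
    subject_id = rep(vapply(cohort, function(w) w$subject_id, ""), n_windows),
    group = rep(vapply(cohort, function(w) w$group, ""), n_windows),
    window_index = unlist(lapply(n_windows, seq_len)),
    state = labels)
  structure(list(
    states = lapply(seq_len(k), function(i) {
      m <- devectorize_upper(centroids[i, ])
      dimnames(m) <- list(cohort[[1]]$region_labels, cohort[[1]]$region_labels)
      m
    }),
    centroids = centroids,
    state_means = rowMeans(centroids),
    occupancy = occupancy,
    assignments = assignments,
    k = k, metric = metric, seed = seed,
    stage1 = list(inertia = stage1$inertia, n_iter = stage1$n_iter,
                  n_reseeds = stage1$n_reseeds,
                  inertia_trace = stage1$inertia_trace),
    stage2 = list(inertia = stage2$inertia, n_iter = stage2$n_iter,
                  n_reseeds = stage2$n_reseeds,
                  inertia_trace = stage2$inertia_trace),
    region_labels = cohort[[1]]$region_labels),
    class = "state_set")
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("<state_set> %d states over %d windows (%s metric)\n",
              x$k, nrow(x$assignments), x$metric))
  cat("  state means: ", paste(sprintf("%.3f", x$state_means),
                               collapse = ", "), "\n")
  cat("  occupancy:   ", paste(sprintf("%.3f", x$occupancy),
                               collapse = ", "), "\n")
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

#' Match one set of state centroids against a reference set
#'
#' Finds the one-to-one pairing maximizing the total Pearson correlation
#' between matched centroids (exhaustive over permutations for K <= 7,
#' greedy beyond).
#'
#' @param centroids K x d matrix to match.
#' @param reference K x d reference matrix.
#' @return list with `perm` (`reference[i, ]` is matched by
#'   `centroids[perm[i], ]`) and `correlation` (per reference state).
#' @export
match_states <- function(centroids, reference) {
  K <- nrow(reference)
  assert_that(nrow(centroids) == K, "centroid sets must have equal size")
  cc <- suppressWarnings(stats::cor(t(reference), t(centroids)))
  cc[!is.finite(cc)] <- -1
  if (K <= 7) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p) sum(cc[cbind(seq_len(K), p)]), 0)
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    taken <- logical(K)
    for (i in order(-apply(cc, 1, max))) {
      j <- which.max(ifelse(taken, -Inf, cc[i, ]))
      perm[i] <- j
      taken[j] <- TRUE
    }
  }
  list(perm = perm, correlation = cc[cbind(seq_len(K), perm)])
}

#' Bootstrap stability of the extracted states
#'
#' Resamples subjects with replacement (keeping the cohort size), reruns
#' the full two-stage extraction on each replicate, and matches the
#' replicate centroids to the full-cohort states. High matched
#' correlations across replicates indicate the states are not artifacts
#' of particular subjects.
#'
#' @param cohort list of `windowed_fc` objects.
#' @param k number of states.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param reference optional precomputed full-cohort `state_set` (computed
#'   here when omitted).
#' @param resample_indices optional list of length `B` giving the subject
#'   indices of each replicate (overrides random resampling; useful to
#'   force the identity replicate).
#' @param ... forwarded to [two_stage_cluster()].
#' @return list with `reference` (the full-cohort `state_set`),
#'   `replicates` (list of `state_set`s) and `similarity` (tibble:
#'   replicate, state, centroid_correlation, occupancy).
#' @export
bootstrap_validate <- function(cohort, k, B = 20, seed = 1,
                               reference = NULL, resample_indices = NULL,
                               ...) {
  assert_that(B >= 1, "B must be at least 1")
  n <- length(cohort)
  reference <- reference %||% two_stage_cluster(cohort, k, seed = seed, ...)
  reps <- vector("list", B)
  sims <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- if (!is.null(resample_indices)) resample_indices[[b]] else {
      set.seed(split_seed(seed, 31, b))
      sample.int(n, n, replace = TRUE)
    }
    boot <- lapply(seq_along(idx), function(i) {
      w <- cohort[[idx[i]]]
      w$subject_id <- sprintf("%s.b%d", w$subject_id, i)  # keep ids unique
      w
    })
    fit <- two_stage_cluster(boot, k, seed = split_seed(seed, 32, b), ...)
    m <- match_states(fit$centroids, reference$centroids)
    reps[[b]] <- fit
    sims[[b]] <- tibble::tibble(
      replicate = b, state = seq_len(k),
      centroid_correlation = m$correlation,
      occupancy = fit$occupancy[m$perm])
  }
  list(reference = reference, replicates = reps,
       similarity = dplyr::bind_rows(sims))
}
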