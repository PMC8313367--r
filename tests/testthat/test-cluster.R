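test_that("manhattan distance is the L1 sum with metric properties", {
  expect_equal(manhattan_distance(c(0, 0), c(1, 2)), 3)
  expect_equal(manhattan_distance(1:5, 1:5), 0)
  set.seed(3)
  a <- rnorm(4005); b <- rnorm(4005); c_ <- rnorm(4005)
  expect_equal(manhattan_distance(a, b), sum(abs(a - b)), tolerance = 1e-12)
  expect_equal(manhattan_distance(a, b), manhattan_distance(b, a))
  expect_lte(manhattan_distance(a, c_),
             manhattan_distance(a, b) + manhattan_distance(b, c_))
  expect_error(manhattan_distance(1:3, 1:4), "equal length")
})

test_that("kmeans++ seeding spreads centers over separated clouds", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 10, 0.3), 20))
  hits <- 0
  for (s in 1:200) {
    C <- kmeans_pp_init(x, 2, seed = s)
    sides <- C[, 1] > 5
    if (sum(sides) == 1) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
  # k = n returns every sample as a center (in some order)
  y <- matrix(c(1, 5, 9), 3, 1)
  C <- kmeans_pp_init(y, 3, seed = 2)
  expect_equal(sort(C[, 1]), c(1, 5, 9))
  C1 <- kmeans_pp_init(y, 1, seed = 7)
  expect_true(C1[, 1] %in% y)
  expect_error(kmeans_pp_init(y, 4, seed = 1), "between 1")
})

test_that("k-means separates clear clouds and respects trivial contracts", {
  x <- matrix(c(0, 0.1, -0.1, 10, 10.1, 9.9), 6, 1)
  fit <- l1_kmeans(x, 2, n_restarts = 5, seed = 1)
  expect_equal(sort(fit$centroids[, 1]), c(0, 10))
  expect_equal(length(unique(fit$labels[1:3])), 1)
  expect_equal(length(unique(fit$labels[4:6])), 1)
  expect_true(fit$labels[1] != fit$labels[4])
  # k distinct points: zero inertia
  z <- matrix(c(1, 4, 9), 3, 1)
  f0 <- l1_kmeans(z, 3, n_restarts = 3, seed = 2)
  expect_equal(f0$inertia, 0)
  expect_equal(sort(f0$labels), 1:3)
  # duplicating all samples doubles inertia, keeps centroids
  fit_dup <- l1_kmeans(rbind(x, x), 2, init_centroids = fit$centroids)
  expect_equal(sort(fit_dup$centroids[, 1]), sort(fit$centroids[, 1]))
  expect_equal(fit_dup$inertia, 2 * fit$inertia)
})

test_that("empty clusters are re-seeded at the farthest sample", {
  x <- matrix(c(0, 0, 0, 10), 4, 1)
  fit <- l1_kmeans(x, 2, init_centroids = matrix(c(0, 100), 2, 1))
  expect_gte(fit$n_reseeds, 1)
  expect_equal(sort(fit$centroids[, 1]), c(0, 10))
})

test_that("the recorded k-means objective never increases", {
  set.seed(8)
  for (rep in 1:20) {
    x <- matrix(rnorm(40 * 6), 40, 6)
    fit <- l1_kmeans(x, sample(2:4, 1), n_restarts = 3, seed = rep)
    expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  }
})

test_that("sample order only permutes labels for a fixed initialization", {
  set.seed(9)
  x <- matrix(rnorm(30 * 4), 30, 4)
  init <- x[c(1, 17), ]
  fit <- l1_kmeans(x, 2, init_centroids = init)
  perm <- sample(30)
  fit_p <- l1_kmeans(x[perm, ], 2, init_centroids = init)
  expect_equal(fit_p$labels, fit$labels[perm])
  expect_equal(fit_p$centroids, fit$centroids)
  expect_equal(fit_p$inertia, fit$inertia)
})

test_that("mean update reproduces the coordinate-wise cluster mean", {
  set.seed(10)
  x <- matrix(rnorm(20 * 3), 20, 3)
  fit <- l1_kmeans(x, 1, metric = "manhattan", update = "mean",
                   n_restarts = 1, seed = 1)
  expect_equal(fit$centroids[1, ], colMeans(x))
  fitm <- l1_kmeans(x, 1, n_restarts = 1, seed = 1)  # default median
  expect_equal(fitm$centroids[1, ], apply(x, 2, median))
})

test_that("exemplar selection ranks windows by FC variance", {
  co <- recovery_cohort()
  wfc <- co$cohort[[1]]
  N <- length(wfc$matrices)
  all_ex <- select_exemplars(wfc, N)
  expect_equal(sort(all_ex$window_index), seq_len(N))
  ex <- select_exemplars(wfc, 7)
  feats <- window_feature_matrix(wfc)
  v <- apply(feats, 1, window_variance)
  expect_equal(ex$window_index, order(-v, seq_len(N))[1:7])
  expect_true(all(ex$variance >= max(v[-ex$window_index])))
  expect_error(select_exemplars(wfc, N + 1), "between 1")
  # ties break toward the earlier window
  wtie <- wfc
  wtie$matrices <- wfc$matrices[c(1, 1, 1)]
  ex2 <- select_exemplars(wtie, 1)
  expect_equal(ex2$window_index, 1)
})

test_that("the effectiveness index finds planted cluster numbers", {
  set.seed(12)
  centers <- matrix(rnorm(4 * 20, sd = 6), 4, 20)
  x <- centers[rep(1:4, each = 40), ] + matrix(rnorm(160 * 20), 160, 20)
  eb <- elbow_select_k(x, k_range = 2:8, seed = 3, n_restarts = 5)
  expect_equal(attr(eb, "chosen_k"), 4)
  two <- rbind(matrix(rnorm(50 * 5), 50, 5), matrix(rnorm(50 * 5, 8), 50, 5))
  eb2 <- elbow_select_k(two, k_range = 2:8, seed = 4, n_restarts = 5)
  expect_equal(attr(eb2, "chosen_k"), 2)
  expect_error(elbow_select_k(matrix(1, 20, 3), seed = 1), "identical")
})

test_that("two-stage clustering orders states by mean and is deterministic", {
  co <- recovery_cohort()
  st <- cached("twostage_small", two_stage_cluster(co$cohort[1:24], 4,
                                                   seed = 5,
                                                   n_restarts = 15))
  expect_s3_class(st, "state_set")
  expect_true(all(diff(st$state_means) < 0))
  expect_equal(sum(st$occupancy), 1, tolerance = 1e-12)
  expect_equal(nrow(st$assignments),
               sum(vapply(co$cohort[1:24], function(w) length(w$matrices), 0)))
  st2 <- two_stage_cluster(co$cohort[1:24], 4, seed = 5, n_restarts = 15)
  expect_identical(st$centroids, st2$centroids)
  expect_identical(st$assignments, st2$assignments)
})

test_that("single-state clustering returns the pooled summary window", {
  co <- recovery_cohort()
  st <- two_stage_cluster(co$cohort[1:4], 1, seed = 2, n_restarts = 2,
                          update = "mean")
  feats <- do.call(rbind, lapply(co$cohort[1:4], window_feature_matrix))
  expect_equal(st$centroids[1, ], colMeans(feats), tolerance = 1e-10)
  expect_equal(st$occupancy, 1)
})

test_that("state matching recovers a known permutation", {
  set.seed(14)
  ref <- matrix(rnorm(4 * 50), 4, 50)
  perm <- c(3, 1, 4, 2)
  noisy <- ref[perm, ] + matrix(rnorm(200, sd = 0.05), 4, 50)
  m <- match_states(noisy, ref)
  expect_equal(m$perm, order(perm))
  expect_true(all(m$correlation > 0.99))
})

test_that("bootstrap with the identity resample reproduces the reference", {
  co <- recovery_cohort()
  st <- cached("twostage_small", two_stage_cluster(co$cohort[1:24], 4,
                                                   seed = 5,
                                                   n_restarts = 15))
  bv <- bootstrap_validate(co$cohort[1:24], 4, B = 1, seed = 5,
                           reference = st,
                           resample_indices = list(seq_len(24)),
                           n_restarts = 15)
  expect_equal(bv$similarity$centroid_correlation, rep(1, 4),
               tolerance = 1e-6)
  expect_equal(bv$similarity$occupancy, st$occupancy, tolerance = 1e-12)
})

test_that("occupancy concentrates on the states the dynamics favor", {
  # switching model whose stationary distribution favors the middle states
  base <- c(0.05, 0.45, 0.45, 0.05)
  P <- matrix(0, 4, 4)
  for (i in 1:4) {
    off <- base[-i] / sum(base[-i]) * 0.03
    P[i, -i] <- off
    P[i, i] <- 0.97
  }
  groups <- list(list(label = "G", n_subjects = 20,
                      model = switching_model(P,
                                              initial_distribution = base)))
  spec <- cohort_spec(groups, n_regions = 16, n_timepoints = 150, seed = 41)
  ch <- generate_cohort(spec)
  cohort <- lapply(ch$subjects, build_windowed_fc, window_seconds = 30)
  st <- two_stage_cluster(cohort, 4, seed = 42, n_restarts = 15)
  expect_gt(st$occupancy[2] + st$occupancy[3], 0.70)
})
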