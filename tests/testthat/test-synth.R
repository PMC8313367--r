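test_that("state covariances hit their mean-FC targets and stay SPD", {
  covs <- make_state_covariances(10, 2, c(0.6, 0.2), seed = 4)
  for (k in 1:2) {
    R <- stats::cov2cor(covs[[k]]$cov)
    expect_equal(mean(R[upper.tri(R)]), c(0.6, 0.2)[k], tolerance = 0.05)
    ev <- eigen(covs[[k]]$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_equal(covs[[k]]$cov, t(covs[[k]]$cov))
  }
})

test_that("degenerate covariance constructions are exact", {
  # zero correlation, no blocks, no jitter: identity
  covs <- make_state_covariances(4, 1, 0, seed = 1, jitter_sd = 0)
  expect_equal(covs[[1]]$cov, diag(4))
  # single pair at level 0.5
  covs <- make_state_covariances(2, 1, 0.5, seed = 1, jitter_sd = 0)
  expect_equal(covs[[1]]$cov[1, 2], 0.5)
  expect_equal(diag(covs[[1]]$cov), c(1, 1))
})

test_that("block structure raises within-block over between-block correlation", {
  blocks <- rep(1:2, each = 6)
  covs <- make_state_covariances(12, 1, 0.3, blocks = blocks, seed = 2)
  R <- stats::cov2cor(covs[[1]]$cov)
  same <- outer(blocks, blocks, `==`) & upper.tri(R)
  diff_ <- !outer(blocks, blocks, `==`) & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff_]))
})

test_that("covariance construction is deterministic given the seed", {
  a <- make_state_covariances(8, 3, c(0.5, 0.3, 0.1), seed = 9,
                              blocks = rep(1:2, each = 4))
  b <- make_state_covariances(8, 3, c(0.5, 0.3, 0.1), seed = 9,
                              blocks = rep(1:2, each = 4))
  expect_identical(a, b)
})

test_that("invalid mean-FC levels are rejected", {
  expect_error(make_state_covariances(5, 2, c(0.2, 0.6), seed = 1),
               "descending")
  expect_error(make_state_covariances(5, 1, 1.2, seed = 1), "\\[0, 1\\)")
})

test_that("switching model validates its transition matrix", {
  expect_error(switching_model(matrix(c(0.5, 0.4, 0.1, 0.9), 2)),
               "sum to 1")
  m <- symmetric_switching(3, 0.8)
  expect_equal(rowSums(m$transition_matrix), rep(1, 3))
  expect_equal(diag(m$transition_matrix), rep(0.8, 3))
})

test_that("label sequences follow the switching model", {
  # single state: constant
  m1 <- symmetric_switching(1)
  expect_equal(sample_label_sequence(m1, 5, seed = 1), rep(1, 5))
  # absorbing start in state 2
  m2 <- switching_model(diag(2), initial_distribution = c(0, 1))
  expect_equal(sample_label_sequence(m2, 8, seed = 3), rep(2, 8))
  # empirical switch rate matches the planted 0.1 at L = 10000
  m3 <- symmetric_switching(2, 0.9)
  labs <- sample_label_sequence(m3, 10000, seed = 11)
  rate <- mean(labs[-1] != labs[-length(labs)])
  expect_equal(rate, 0.1, tolerance = 0.01)
})

test_that("subject sampling reproduces the planted covariance", {
  covs <- make_state_covariances(6, 1, 0.4, seed = 5,
                                 blocks = rep(1:2, each = 3))
  ts <- sample_subject(rep(1, 50000), covs, noise_sd = 0, seed = 8)
  emp <- stats::cov(ts$data)
  rel <- norm(emp - covs[[1]]$cov, "F") / norm(covs[[1]]$cov, "F")
  expect_lt(rel, 0.05)
})

test_that("subject sampling is deterministic and validates inputs", {
  covs <- list(diag(4))
  a <- sample_subject(rep(1, 30), covs, noise_sd = 0.3, seed = 2)
  b <- sample_subject(rep(1, 30), covs, noise_sd = 0.3, seed = 2)
  expect_identical(a$data, b$data)
  expect_error(sample_subject(integer(0), covs, seed = 1))
  expect_error(sample_subject(rep(2, 30), covs, seed = 1), "labels")
})

test_that("cohort generation yields one subject per slot, deterministically", {
  spec <- mci_like_cohort_spec(n_per_group = c(NC = 3, eMCI = 2, lMCI = 2),
                               n_regions = 8, n_timepoints = 40, seed = 6)
  a <- generate_cohort(spec)
  expect_length(a$subjects, 7)
  expect_equal(nrow(a$manifest), 7)
  expect_setequal(unique(a$manifest$group), c("eMCI", "lMCI", "NC"))
  expect_length(a$truth$labels, 7)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$subjects, `[[`, "data"),
                   lapply(b$subjects, `[[`, "data"))
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("the study-sized cohort has 160 subjects split 48/45/67", {
  spec <- mci_like_cohort_spec(n_regions = 5, n_timepoints = 20, seed = 1)
  ch <- generate_cohort(spec)
  counts <- table(ch$manifest$group)
  expect_equal(unname(counts[c("eMCI", "lMCI", "NC")]),
               c(48, 45, 67), ignore_attr = TRUE)
  expect_equal(length(ch$subjects), 160)
})

test_that("per-group covariance deltas perturb only the targeted group", {
  delta <- matrix(0, 6, 6)
  delta[1, 2] <- delta[2, 1] <- -0.3
  groups <- list(
    list(label = "A", n_subjects = 1, model = symmetric_switching(2, 0.9)),
    list(label = "B", n_subjects = 1, model = symmetric_switching(2, 0.9),
         cov_deltas = list(list(state = 1, delta = delta))))
  spec <- cohort_spec(groups, n_regions = 6, n_timepoints = 30000,
                      mean_fc_levels = c(0.5, 0.2), noise_sd = 0, seed = 3)
  ch <- generate_cohort(spec)
  labs_a <- ch$truth$labels[["A_01"]]
  labs_b <- ch$truth$labels[["B_01"]]
  ra <- cor(ch$subjects[[1]]$data[labs_a == 1, 1:2])[1, 2]
  rb <- cor(ch$subjects[[2]]$data[labs_b == 1, 1:2])[1, 2]
  expect_lt(rb, ra - 0.15)
})
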