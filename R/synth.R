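#' Construct planted connectivity-state covariance matrices
#'
#' Builds `K` symmetric positive-definite covariance (correlation-scaled)
#' matrices whose mean off-diagonal correlation matches a prescribed,
#' strictly descending set of levels — the generative analogue of a set of
#' recurring functional connectivity states ranked by mean connectivity.
#' An optional module partition plants community structure: within-block
#' correlations are raised and between-block correlations lowered so the
#' overall mean stays on target.
#'
#' @param M number of regions (>= 2).
#' @param K number of states.
#' @param mean_fc_levels length-`K` vector of target mean off-diagonal
#'   correlations, strictly descending, each in `[0, 1)`.
#' @param blocks optional integer vector of length `M` assigning each region
#'   to a module; `NULL` for no block structure. States after the first
#'   apply the partition to a seeded random permutation of the regions, so
#'   states differ in pattern (which regions cohere), not just in level.
#' @param block_contrast how much within-block correlation exceeds the state
#'   mean (capped so entries stay below 0.95).
#' @param seed integer seed controlling the small symmetric jitter that
#'   decorrelates states beyond their block layout.
#' @param jitter_sd sd of the symmetric entrywise jitter (0 disables).
#' @return list of `K` state covariance objects, each a list with
#'   `state_id`, `cov` (M x M SPD), `target_mean_fc`, and `spd_repairs`
#'   (number of diagonal-loading doublings needed, usually 0).
#' @export
#' @examples
#' covs <- make_state_covariances(10, 2, c(0.6, 0.2), seed = 1)
#' mean(covs[[1]]$cov[upper.tri(covs[[1]]$cov)])
make_state_covariances <- function(M, K, mean_fc_levels, blocks = NULL,
                                   block_contrast = 0.3, seed = 1,
                                   jitter_sd = 0.02) {
  assert_that(M >= 2, "M must be at least 2")
  assert_that(length(mean_fc_levels) == K, "need one mean FC level per state")
  assert_that(all(mean_fc_levels >= 0 & mean_fc_levels < 1),
              "mean FC levels must lie in [0, 1)")
  if (K > 1) {
    assert_that(all(diff(mean_fc_levels) < 0),
                "mean FC levels must be strictly descending")
  }
  if (!is.null(blocks)) {
    assert_that(length(blocks) == M, "blocks must have one entry per region")
  }
  set.seed(split_seed(seed, 101))
  lapply(seq_len(K), function(k) {
    lev <- mean_fc_levels[k]
    R <- matrix(lev, M, M)
    if (!is.null(blocks) && length(unique(blocks)) > 1) {
      # each state groups a different (seeded) permutation of the regions
      # into the blocks, so any two states differ in pattern by a similar,
      # large margin rather than only in overall level
      blk <- if (k == 1) blocks else blocks[sample.int(M)]
      same <- outer(blk, blk, `==`)
      n_within <- sum(same[upper.tri(same)])
      n_between <- M * (M - 1) / 2 - n_within
      within <- min(lev + block_contrast, 0.95)
      between <- (lev * (n_within + n_between) - within * n_within) / n_between
      between <- max(between, -0.9 / (M - 1))  # keep near-PD equicorrelation
      R[same] <- within
      R[!same] <- between
    }
    if (jitter_sd > 0) {
      J <- matrix(rnorm(M * M, sd = jitter_sd), M, M)
      R <- R + (J + t(J)) / 2
    }
    diag(R) <- 1
    rep_spd <- repair_spd(R)
    cov <- stats::cov2cor(rep_spd$mat)  # back to unit diagonal after loading
    emp <- mean(cov[upper.tri(cov)])
    if (abs(emp - lev) > 0.05) {
      stop(sprintf("state %d mean correlation %.3f misses target %.3f", k,
                   emp, lev), call. = FALSE)
    }
    list(state_id = k, cov = cov, target_mean_fc = lev,
         spd_repairs = rep_spd$n_repairs)
  })
}

# Diagonal loading: add eps * I, doubling eps until all eigenvalues positive.
repair_spd <- function(R, eps0 = 1e-6, max_repairs = 60) {
  n <- 0
  eps <- eps0
  repeat {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10) return(list(mat = R, n_repairs = n))
    if (n >= max_repairs) {
      stop("could not repair matrix to positive definiteness", call. = FALSE)
    }
    R <- R + diag(eps, nrow(R))
    eps <- eps * 2
    n <- n + 1
  }
}

#' Define a Markov state-switching model
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_distribution length-K probability vector; defaults to the
#'   uniform distribution.
#' @return a `switching_model` object.
#' @export
#' @examples
#' switching_model(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
switching_model <- function(transition_matrix,
                            initial_distribution = NULL) {
  P <- as.matrix(transition_matrix)
  K <- nrow(P)
  assert_that(ncol(P) == K, "transition matrix must be square")
  assert_that(all(P >= 0 & P <= 1), "transition probabilities must be in [0, 1]")
  assert_that(all(abs(rowSums(P) - 1) < 1e-12),
              "transition matrix rows must sum to 1")
  pi0 <- initial_distribution %||% rep(1 / K, K)
  assert_that(length(pi0) == K && abs(sum(pi0) - 1) < 1e-12 && all(pi0 >= 0),
              "initial distribution must be a length-K probability vector")
  structure(list(n_states = K, transition_matrix = P,
                 initial_distribution = pi0),
            class = "switching_model")
}

#' Convenience constructor: symmetric switching with a common dwell probability
#'
#' @param K number of states.
#' @param self_transition probability of staying in the current state; the
#'   remainder is spread evenly over the other states.
#' @return a `switching_model`.
#' @export
symmetric_switching <- function(K, self_transition = 0.9) {
  assert_that(self_transition >= 0 && self_transition <= 1,
              "self_transition must be in [0, 1]")
  if (K == 1) return(switching_model(matrix(1, 1, 1)))
  off <- (1 - self_transition) / (K - 1)
  P <- matrix(off, K, K)
  diag(P) <- self_transition
  switching_model(P)
}

#' Sample a state label sequence from a switching model
#'
#' @param model a [switching_model()].
#' @param L sequence length (>= 1).
#' @param seed integer seed.
#' @return integer vector of length `L` with labels in `1..K`.
#' @export
sample_label_sequence <- function(model, L, seed) {
  assert_that(inherits(model, "switching_model"), "model must be a switching_model")
  assert_that(L >= 1, "L must be at least 1")
  set.seed(seed)
  K <- model$n_states
  labels <- integer(L)
  labels[1] <- sample.int(K, 1, prob = model$initial_distribution)
  if (L > 1) {
    for (t in 2:L) {
      labels[t] <- sample.int(K, 1, prob = model$transition_matrix[labels[t - 1], ])
    }
  }
  labels
}

#' Bundle one subject's region time series with its metadata
#'
#' @param data L x M numeric matrix (time points by regions).
#' @param subject_id,group identifier strings.
#' @param tr_seconds sampling interval in seconds.
#' @param region_labels optional region names (default `R1..RM`).
#' @return a `roi_timeseries` object.
#' @export
roi_timeseries <- function(data, subject_id, group = NA_character_,
                           tr_seconds = 2, region_labels = NULL) {
  data <- as.matrix(data)
  assert_that(nrow(data) > 1, "time series needs more than one time point")
  assert_that(all(is.finite(data)), "time series must be finite")
  labels <- region_labels %||% paste0("R", seq_len(ncol(data)))
  assert_that(length(labels) == ncol(data), "one label per region required")
  colnames(data) <- labels
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group), data = data,
                 tr_seconds = tr_seconds, region_labels = labels),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s (group %s): %d time points x %d regions, TR = %gs\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Simulate one subject's ROI time series from a planted label sequence
#'
#' Each time point is an independent draw from a zero-mean multivariate
#' normal with the covariance of the currently active state, plus optional
#' isotropic Gaussian observation noise. No within-state autocorrelation is
#' modelled, so windowed Pearson correlation is a consistent estimator of
#' the active state's correlation pattern.
#'
#' @param labels integer state sequence (length L).
#' @param covs list of state covariance objects (from
#'   [make_state_covariances()]) or plain covariance matrices, indexed by
#'   the label values.
#' @param noise_sd sd of added isotropic noise (>= 0).
#' @param seed integer seed.
#' @param subject_id,group,tr_seconds metadata forwarded to
#'   [roi_timeseries()].
#' @return a `roi_timeseries`.
#' @export
sample_subject <- function(labels, covs, noise_sd = 0, seed = 1,
                           subject_id = "S1", group = NA_character_,
                           tr_seconds = 2) {
  L <- length(labels)
  assert_that(L >= 2, "need at least two time points")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  mats <- lapply(covs, function(cv) if (is.list(cv)) cv$cov else as.matrix(cv))
  M <- ncol(mats[[1]])
  assert_that(all(vapply(mats, ncol, 1L) == M), "state covariances disagree in size")
  assert_that(all(labels >= 1 & labels <= length(mats)),
              "labels index states outside the covariance list")
  chols <- lapply(mats, function(cv) chol(cv))  # upper-triangular factors
  set.seed(seed)
  Z <- matrix(rnorm(L * M), L, M)
  X <- matrix(0, L, M)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    X[idx, ] <- Z[idx, , drop = FALSE] %*% chols[[s]]
  }
  if (noise_sd > 0) X <- X + matrix(rnorm(L * M, sd = noise_sd), L, M)
  roi_timeseries(X, subject_id = subject_id, group = group,
                 tr_seconds = tr_seconds)
}

#' Specify a synthetic multi-group cohort
#'
#' @param groups list of group definitions, each a list with `label`,
#'   `n_subjects`, `model` (a [switching_model()]), and optionally
#'   `cov_deltas` — a list of `list(state =, delta =)` entries adding a
#'   symmetric per-edge perturbation to that state's covariance for this
#'   group only (an edge-level group effect).
#' @param n_regions M (>= 3).
#' @param n_timepoints L.
#' @param mean_fc_levels per-state target mean correlations, descending.
#' @param blocks module partition forwarded to [make_state_covariances()];
#'   defaults to three roughly equal blocks.
#' @param tr_seconds repetition time in seconds.
#' @param noise_sd isotropic observation noise sd.
#' @param seed master seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(groups, n_regions = 30, n_timepoints = 150,
                        mean_fc_levels = c(0.58, 0.39, 0.25, 0.20),
                        blocks = NULL, block_contrast = 0.3,
                        tr_seconds = 2, noise_sd = 0.2, seed = 1) {
  assert_that(n_regions >= 3, "need at least three regions")
  K <- length(mean_fc_levels)
  for (g in groups) {
    assert_that(!is.null(g$label) && !is.null(g$n_subjects) && !is.null(g$model),
                "each group needs label, n_subjects and model")
    assert_that(g$n_subjects >= 1, "each group needs at least one subject")
    assert_that(g$model$n_states == K,
                "group switching model must have one state per FC level")
  }
  blocks <- blocks %||% sort(rep_len(seq_len(3), n_regions))
  structure(list(groups = groups, n_regions = n_regions,
                 n_timepoints = n_timepoints,
                 mean_fc_levels = mean_fc_levels, blocks = blocks,
                 block_contrast = block_contrast,
                 tr_seconds = tr_seconds, noise_sd = noise_sd, seed = seed,
                 n_states = K),
            class = "cohort_spec")
}

#' Cohort specification mirroring a three-group MCI study design
#'
#' Three groups — normal controls, early and late mild cognitive impairment —
#' sharing one set of planted states but differing in switching dynamics:
#' controls dwell longest (self-transition 0.95) and the late-impairment
#' group switches most (0.80), so transition-count group differences are
#' planted by construction.
#'
#' @param n_per_group named vector of group sizes (`NC`, `eMCI`, `lMCI`).
#' @param self_transitions named vector of self-transition probabilities.
#' @param ... forwarded to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
mci_like_cohort_spec <- function(n_per_group = c(NC = 67, eMCI = 48, lMCI = 45),
                                 self_transitions = c(NC = 0.95, eMCI = 0.90,
                                                      lMCI = 0.80),
                                 ...) {
  dots <- list(...)
  K <- length(dots$mean_fc_levels %||% c(0.58, 0.39, 0.25, 0.20))
  groups <- lapply(names(n_per_group), function(lab) {
    list(label = lab, n_subjects = unname(n_per_group[[lab]]),
         model = symmetric_switching(K, self_transitions[[lab]]))
  })
  do.call(cohort_spec, c(list(groups = groups), dots))
}

#' Cohort specification for state-recovery studies
#'
#' Three equal groups with slow, shared switching dynamics (long dwells
#' relative to the window length) and strongly modular planted states, so
#' that most windows are pure samples of one state and the states are
#' clearly separated — the regime in which window-level state recovery is
#' identifiable at all. Use [mci_like_cohort_spec()] when group-specific
#' dynamics are the object of study.
#'
#' @param n_per_group subjects per group (default 30 each).
#' @param self_transition shared dwell probability (default 0.98; mean
#'   dwell 50 time points, about 3 windows at 15 TRs).
#' @param ... forwarded to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
state_recovery_cohort_spec <- function(n_per_group = c(NC = 30, eMCI = 30,
                                                       lMCI = 30),
                                       self_transition = 0.98, ...) {
  mci_like_cohort_spec(
    n_per_group = n_per_group,
    self_transitions = setNames(rep(self_transition, length(n_per_group)),
                                names(n_per_group)), ...)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws every subject's label sequence from its group's switching model and
#' the region signals from the planted state covariances. Fully
#' deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (list of `roi_timeseries`), `manifest`
#'   (tibble: subject_id, group) and `truth` (planted labels per subject,
#'   state covariances, per-group transition matrices).
#' @export
#' @examples
#' spec <- mci_like_cohort_spec(n_per_group = c(NC = 2, eMCI = 2, lMCI = 2),
#'                              n_regions = 10, n_timepoints = 60, seed = 7)
#' cohort <- generate_cohort(spec)
#' cohort$manifest
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  covs <- make_state_covariances(spec$n_regions, spec$n_states,
                                 spec$mean_fc_levels, blocks = spec$blocks,
                                 block_contrast = spec$block_contrast %||% 0.3,
                                 seed = split_seed(spec$seed, 1))
  subjects <- list()
  labels_by_subject <- list()
  manifest <- list()
  subj_counter <- 0
  for (gi in seq_along(spec$groups)) {
    grp <- spec$groups[[gi]]
    gcovs <- covs
    for (dlt in grp$cov_deltas %||% list()) {
      s <- dlt$state
      pert <- gcovs[[s]]$cov + as.matrix(dlt$delta)
      gcovs[[s]]$cov <- repair_spd(pert)$mat
    }
    for (si in seq_len(grp$n_subjects)) {
      subj_counter <- subj_counter + 1
      sid <- sprintf("%s_%02d", grp$label, si)
      lab_seed <- split_seed(spec$seed, 2, gi, si)
      labels <- sample_label_sequence(grp$model, spec$n_timepoints, lab_seed)
      ts_seed <- split_seed(spec$seed, 3, gi, si)
      subjects[[subj_counter]] <- sample_subject(
        labels, gcovs, noise_sd = spec$noise_sd, seed = ts_seed,
        subject_id = sid, group = grp$label, tr_seconds = spec$tr_seconds)
      labels_by_subject[[sid]] <- labels
      manifest[[subj_counter]] <- tibble::tibble(subject_id = sid,
                                                 group = grp$label)
    }
  }
  truth <- list(
    labels = labels_by_subject,
    state_covariances = covs,
    transition_matrices = setNames(
      lapply(spec$groups, function(g) g$model$transition_matrix),
      vapply(spec$groups, function(g) g$label, "")),
    spec = spec)
  list(subjects = subjects, manifest = dplyr::bind_rows(manifest),
       truth = truth)
}
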