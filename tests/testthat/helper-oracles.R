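# Independent brute-force oracles used to cross-check the package's graph,
# clustering and statistics code. Deliberately naive implementations:
# nothing here shares code with the package internals under test.

# Erdos-Renyi adjacency matrix (symmetric, zero diagonal)
random_binary_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

oracle_degree <- function(A) {
  vapply(seq_len(nrow(A)), function(i) sum(A[i, ] != 0), 0)
}

# triangle count by explicit triple enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(A[i, ] != 0)
    if (k < 2) return(0)
    tri <- 0
    nb <- which(A[i, ] != 0)
    for (a in seq_along(nb)) {
      for (b in seq_len(a - 1)) {
        if (A[nb[a], nb[b]] != 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, 0)
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_char_path_length <- function(D) {
  n <- nrow(D)
  Li <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) > 0) Li[i] <- mean(d)
  }
  mean(Li, na.rm = TRUE)
}

oracle_global_efficiency <- function(D) {
  n <- nrow(D)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    Dn <- oracle_floyd_warshall(A[nb, nb, drop = FALSE])
    tot <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b && is.finite(Dn[a, b])) tot <- tot + 1 / Dn[a, b]
      }
    }
    tot / (k * (k - 1))
  }, 0)
}

oracle_participation <- function(A, part) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(A[i, ] != 0)
    if (k == 0) return(0)
    s <- 0
    for (m in unique(part)) {
      km <- sum(A[i, part == m] != 0)
      s <- s + (km / k)^2
    }
    1 - s
  }, 0)
}

oracle_within_module_z <- function(A, part) {
  n <- nrow(A)
  kappa <- vapply(seq_len(n), function(i) sum(A[i, part == part[i]] != 0), 0)
  z <- numeric(n)
  for (m in unique(part)) {
    idx <- which(part == m)
    mu <- mean(kappa[idx])
    sdm <- sqrt(sum((kappa[idx] - mu)^2) / length(idx))
    z[idx] <- if (sdm == 0) 0 else (kappa[idx] - mu) / sdm
  }
  z
}

# Exhaustive 1-D k-medians (L1) optimum. For L1 cost with median centers an
# optimal partition is contiguous in sorted order, so enumerating all
# contiguous partitions into at most k blocks is exhaustive.
oracle_kmedians_1d <- function(x, k) {
  n <- length(x)
  xs <- sort(x)
  cost_block <- function(lo, hi) sum(abs(xs[lo:hi] - stats::median(xs[lo:hi])))
  best <- Inf
  cuts_list <- c(list(integer(0)),
                 if (k > 1) unlist(lapply(seq_len(k - 1), function(nb) {
                   utils::combn(n - 1, nb, simplify = FALSE)
                 }), recursive = FALSE))
  for (cuts in cuts_list) {
    bounds <- c(0, cuts, n)
    tot <- 0
    for (b in seq_len(length(bounds) - 1)) {
      tot <- tot + cost_block(bounds[b] + 1, bounds[b + 1])
    }
    if (tot < best) best <- tot
  }
  best
}

# Fisher-Z of a correlation matrix of a planted state covariance, with the
# diagonal convention used throughout the pipeline
planted_state_features <- function(truth) {
  do.call(rbind, lapply(truth$state_covariances, function(s) {
    z <- fisher_z(stats::cov2cor(s$cov))
    diag(z) <- 0
    vectorize_upper(z)
  }))
}

# majority planted state of each window of each subject, in cohort order
window_majority_labels <- function(cohort, truth) {
  unlist(lapply(cohort, function(w) {
    labs <- truth$labels[[w$subject_id]]
    vapply(w$window_start_indices, function(s) {
      seg <- labs[(s + 1):(s + w$window_length_tr)]
      tb <- table(seg)
      as.integer(names(tb)[which.max(tb)])
    }, 0L)
  }))
}

# hand-rolled step-up FDR (independent of stats::p.adjust)
oracle_bh_mask <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  keep <- logical(n)
  kmax <- 0
  for (i in seq_len(n)) {
    if (p[ord[i]] <= q * i / n) kmax <- i
  }
  if (kmax > 0) keep[ord[seq_len(kmax)]] <- TRUE
  keep
}

# cache for expensive shared fixtures (built once per test run)
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

recovery_cohort <- function(seed = 77) {
  cached(paste0("recovery_", seed), {
    spec <- state_recovery_cohort_spec(self_transition = 0.99, seed = seed)
    ch <- generate_cohort(spec)
    list(cohort = lapply(ch$subjects, build_windowed_fc,
                         window_seconds = 30),
         truth = ch$truth, subjects = ch$subjects)
  })
}
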