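#' Sliding-window start indices
#'
#' Zero-based, half-open windows `[start, start + w)` advanced by `step`
#' until the window would overrun the series.
#'
#' @param L series length in TRs.
#' @param w window length in TRs (`1 <= w <= L`).
#' @param step step length in TRs (>= 1).
#' @return integer vector of start indices.
#' @export
#' @examples
#' window_starts(100, 20, 5)
window_starts <- function(L, w, step = 1) {
  assert_that(w >= 1 && step >= 1, "window and step must be positive")
  if (w > L) stop("window longer than series", call. = FALSE)
  seq.int(0L, L - w, by = step)
}

#' Pearson correlation matrix of one window
#'
#' @param window w x M numeric matrix (one window of the time series).
#' @param window_index index used in error messages.
#' @return M x M correlation matrix, unit diagonal.
#' @export
pearson_fc <- function(window, window_index = NA) {
  assert_that(nrow(window) >= 3, "window must span at least three time points")
  sds <- apply(window, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(window)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("constant signal for region %s in window %s", nm,
                 window_index), call. = FALSE)
  }
  stats::cor(window)
}

#' Fisher R-Z transform of correlations
#'
#' `z = 0.5 * log((1 + r) / (1 - r))` — the variance-stabilizing transform
#' applied to every windowed correlation before clustering. Correlations
#' within `1e-7` of +/-1 are clamped so self-correlations and numerically
#' degenerate pairs stay finite.
#'
#' @param r scalar, vector or matrix of correlations with `|r| <= 1`.
#' @return the transformed values, same shape as `r`.
#' @export
#' @examples
#' fisher_z(0.5)
#' fisher_z(c(-0.9, 0, 0.9))
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  clamp <- 1 - 1e-7
  r <- pmin(pmax(r, -clamp), clamp)
  # computed on |r| and signed, so odd symmetry FZ(-r) = -FZ(r) is exact
  a <- abs(r)
  sign(r) * (0.5 * log((1 + a) / (1 - a)))
}

#' Inverse Fisher R-Z transform
#' @param z Fisher-Z values.
#' @return correlations in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Build a subject's sequence of windowed Fisher-Z connectivity matrices
#'
#' Slides a rectangular (untapered) window over the series, computes the
#' Pearson correlation matrix in each window, applies the Fisher R-Z
#' transform, and zeroes the diagonal (the self-correlation is identically
#' 1 and carries no information; it is excluded from all downstream
#' vectors and metrics).
#'
#' @param ts a [roi_timeseries()].
#' @param window_seconds window length in seconds; converted to TRs as
#'   `round(window_seconds / tr_seconds)`. Ignored when `window_tr` given.
#' @param window_tr window length directly in TRs.
#' @param step_tr step length in TRs.
#' @return a `windowed_fc` object: list with `subject_id`, `group`,
#'   `matrices` (list of M x M Fisher-Z matrices, zero diagonal),
#'   `window_start_indices` (0-based), `window_length_tr`, `step_tr`,
#'   `region_labels`, `tr_seconds`.
#' @export
#' @examples
#' ts <- sample_subject(rep(1, 60), list(diag(5)), seed = 1)
#' wfc <- build_windowed_fc(ts, window_seconds = 30)
#' length(wfc$matrices)
build_windowed_fc <- function(ts, window_seconds = 30, window_tr = NULL,
                              step_tr = 1) {
  assert_that(inherits(ts, "roi_timeseries"), "ts must be a roi_timeseries")
  w <- window_tr %||% as.integer(round(window_seconds / ts$tr_seconds))
  L <- nrow(ts$data)
  starts <- window_starts(L, w, step_tr)
  mats <- lapply(seq_along(starts), function(n) {
    s <- starts[n]
    fc <- pearson_fc(ts$data[(s + 1):(s + w), , drop = FALSE],
                     window_index = n)
    z <- fisher_z(fc)
    diag(z) <- 0
    z
  })
  structure(list(subject_id = ts$subject_id, group = ts$group,
                 matrices = mats, window_start_indices = starts,
                 window_length_tr = w, step_tr = step_tr,
                 region_labels = ts$region_labels,
                 tr_seconds = ts$tr_seconds),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("<windowed_fc> subject %s: %d windows of %d TRs (step %d), %d regions\n",
              x$subject_id, length(x$matrices), x$window_length_tr,
              x$step_tr, length(x$region_labels)))
  invisible(x)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-major upper triangle excluding the diagonal — the feature vector a
#' window contributes to clustering (length `M(M-1)/2`; 4005 for the 90
#' regions of the AAL atlas).
#'
#' @param m symmetric M x M matrix.
#' @return numeric vector of length `M(M-1)/2`.
#' @seealso [devectorize_upper()]
#' @export
vectorize_upper <- function(m) {
  assert_that(is.matrix(m) && nrow(m) == ncol(m), "input must be square")
  t(m)[lower.tri(m)]  # transpose trick gives row-major upper-triangle order
}

#' Restore a symmetric matrix from its upper-triangle vector
#'
#' @param v vector from [vectorize_upper()].
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric matrix.
#' @export
devectorize_upper <- function(v, diag_value = 0) {
  M <- (1 + sqrt(1 + 8 * length(v))) / 2
  assert_that(abs(M - round(M)) < 1e-9, "length is not a triangular number")
  M <- as.integer(round(M))
  tm <- matrix(0, M, M)
  tm[lower.tri(tm)] <- v
  m <- t(tm) + tm
  diag(m) <- diag_value
  m
}

#' Variance of a window's connectivity vector
#'
#' Population variance (denominator `n`) of the vectorized FC entries,
#' the ranking statistic for exemplar selection: transition-spanning
#' windows mix states and show inflated variance across edges.
#'
#' @param v numeric vector (length >= 2).
#' @return scalar population variance.
#' @export
window_variance <- function(v) {
  assert_that(length(v) >= 2, "need at least two entries")
  mean((v - mean(v))^2)
}

#' Stack a subject's windows into a feature matrix
#'
#' @param wfc a `windowed_fc`.
#' @return N x M(M-1)/2 matrix, one row per window.
#' @export
window_feature_matrix <- function(wfc) {
  do.call(rbind, lapply(wfc$matrices, vectorize_upper))
}
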