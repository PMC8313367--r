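#' Mean dwelling time of a state
#'
#' Mean length, in windows, of the maximal uninterrupted runs of `state`
#' within a subject's window-state sequence. A state never visited has
#' dwell time 0 (with zero visits).
#'
#' @param labels integer state sequence.
#' @param state state of interest.
#' @return scalar mean run length in windows.
#' @export
#' @examples
#' mean_dwell_time(c(1, 1, 2, 2, 2, 1), 2)
#' mean_dwell_time(c(1, 1, 2, 2, 2, 1), 1)
mean_dwell_time <- function(labels, state) {
  r <- rle(labels)
  runs <- r$lengths[r$values == state]
  if (length(runs) == 0) return(0)
  mean(runs)
}

#' Number of state transitions in a label sequence
#'
#' @param labels integer state sequence (length >= 1).
#' @return count of adjacent unequal label pairs.
#' @export
#' @examples
#' n_transitions(c(1, 2, 3, 3))
n_transitions <- function(labels) {
  assert_that(length(labels) >= 1, "empty label sequence")
  sum(labels[-1] != labels[-length(labels)])
}

#' Fraction of windows spent in each state
#'
#' @param labels integer state sequence.
#' @param K number of states.
#' @return length-K vector of occupancies summing to 1.
#' @export
state_fractions <- function(labels, K) {
  assert_that(all(labels >= 1 & labels <= K), "labels outside 1..K")
  tabulate(labels, K) / length(labels)
}

#' Per-subject temporal state dynamics
#'
#' Summarizes every subject's window-state sequence: per-state occupancy
#' fraction, mean dwelling time and number of visits, plus the subject's
#' total transition count. Dwell times are reported in windows; multiply
#' by `step_tr * tr_seconds` for seconds.
#'
#' @param assignments tibble with columns `subject_id`, `group`,
#'   `window_index`, `state` (as produced by [two_stage_cluster()]), or a
#'   `state_set`.
#' @param K number of states (inferred from a `state_set`).
#' @return list of two tibbles: `per_state` (subject_id, group, state,
#'   fraction, mean_dwell, n_visits) and `per_subject` (subject_id, group,
#'   n_windows, n_transitions).
#' @export
compute_dynamics <- function(assignments, K = NULL) {
  if (inherits(assignments, "state_set")) {
    K <- assignments$k
    assignments <- assignments$assignments
  }
  K <- K %||% max(assignments$state)
  asn <- dplyr::arrange(assignments, .data$subject_id, .data$window_index)
  per_subject <- asn |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(n_windows = dplyr::n(),
                     n_transitions = n_transitions(.data$state),
                     .groups = "drop")
  per_state <- asn |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::reframe(dynamics_one(.data$state, K))
  list(per_state = per_state, per_subject = per_subject)
}

dynamics_one <- function(labels, K) {
  r <- rle(labels)
  tibble::tibble(
    state = seq_len(K),
    fraction = state_fractions(labels, K),
    mean_dwell = vapply(seq_len(K), function(s) mean_dwell_time(labels, s), 0),
    n_visits = vapply(seq_len(K), function(s) sum(r$values == s), 0))
}

#' Two-sample t-test between groups
#'
#' Student's pooled-variance two-sample t by default (the classic form
#' used for dwell-time and transition-count comparisons); Welch's
#' unequal-variance form behind `welch = TRUE`. When both groups are
#' constant and equal the test is degenerate and `t = 0, p = 1` by
#' convention.
#'
#' @param values numeric outcome, one per subject.
#' @param groups group label per subject.
#' @param pair character vector of the two labels to compare, in order
#'   (`t > 0` means the first group has the larger mean); defaults to the
#'   two labels present.
#' @param welch use Welch's correction.
#' @return one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3, 8, 9, 10), rep(c("a", "b"), each = 3))
group_compare <- function(values, groups, pair = NULL, welch = FALSE) {
  pair <- pair %||% unique(groups)[1:2]
  a <- values[groups == pair[1]]
  b <- values[groups == pair[2]]
  assert_that(length(a) >= 2 && length(b) >= 2,
              "each group needs at least two subjects")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (!is.finite(se) || se == 0) {
    tt <- if (isTRUE(all.equal(mean(a), mean(b)))) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (tt == 0) 1 else 0
    if (!is.finite(df)) df <- na + nb - 2
  } else {
    tt <- (mean(a) - mean(b)) / se
    p <- 2 * pt(-abs(tt), df)
  }
  tibble::tibble(group_a = pair[1], group_b = pair[2], n_a = na, n_b = nb,
                 mean_a = mean(a), mean_b = mean(b), t = tt, df = df, p = p)
}

#' Group comparisons of all dynamics metrics
#'
#' Runs the two-sample t-test for every pair of groups on transition
#' counts and, per state, on occupancy fraction and mean dwelling time.
#' Subjects who never visit a state are excluded from that state's
#' dwell-time test (absence is not the same as a short dwell); the number
#' excluded is reported.
#'
#' @param dynamics result of [compute_dynamics()].
#' @param welch forwarded to [group_compare()].
#' @return tibble with columns `metric`, `state` (NA for transition
#'   counts), the [group_compare()] columns and `n_excluded`.
#' @export
compare_dynamics <- function(dynamics, welch = FALSE) {
  per_subject <- dynamics$per_subject
  per_state <- dynamics$per_state
  groups <- sort(unique(per_subject$group))
  pairs <- if (length(groups) >= 2) combn(groups, 2, simplify = FALSE) else list()
  out <- list()
  for (pr in pairs) {
    sel <- per_subject$group %in% pr
    row <- group_compare(per_subject$n_transitions[sel],
                         per_subject$group[sel], pair = pr, welch = welch)
    out[[length(out) + 1]] <- dplyr::mutate(row, metric = "n_transitions",
                                            state = NA_integer_,
                                            n_excluded = 0L)
    for (s in sort(unique(per_state$state))) {
      ps <- per_state[per_state$state == s & per_state$group %in% pr, ]
      row <- group_compare(ps$fraction, ps$group, pair = pr, welch = welch)
      out[[length(out) + 1]] <- dplyr::mutate(row, metric = "fraction",
                                              state = s, n_excluded = 0L)
      visited <- ps[ps$n_visits > 0, ]
      n_excl <- nrow(ps) - nrow(visited)
      if (all(table(factor(visited$group, levels = pr)) >= 2)) {
        row <- group_compare(visited$mean_dwell, visited$group, pair = pr,
                             welch = welch)
        out[[length(out) + 1]] <- dplyr::mutate(row, metric = "mean_dwell",
                                                state = s,
                                                n_excluded = n_excl)
      }
    }
  }
  dplyr::relocate(dplyr::bind_rows(out), "metric", "state")
}
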