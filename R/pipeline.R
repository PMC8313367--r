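#' Run the full dynamic connectivity state pipeline
#'
#' Orchestrates the whole analysis on a cohort of subjects: windowed
#' Fisher-Z connectivity, elbow-rule (or fixed) choice of the number of
#' states, two-stage state extraction, temporal dynamics with group
#' comparisons, graph indicators per state, and NBS edge-wise group tests
#' within the most occupied states. A single master seed drives every
#' stochastic stage through [split_seed()].
#'
#' @param subjects list of [roi_timeseries()] objects, or the result of
#'   [generate_cohort()].
#' @param window_seconds sliding-window length in seconds (default 30;
#'   converted per subject as `round(window_seconds / tr_seconds)` TRs).
#' @param step_tr window step in TRs (default 1).
#' @param k number of states, or `"auto"` for elbow-rule selection over
#'   `k_range` on the pooled exemplars.
#' @param k_range candidate k for the elbow rule (default `2:10`).
#' @param n_exemplars high-variance exemplar windows per subject
#'   (default 7).
#' @param metric clustering distance (default `"manhattan"`).
#' @param n_restarts stage-1 restarts (default 50).
#' @param tau graph disconnection threshold (default 0.3).
#' @param nbs_threshold primary |t| threshold for NBS (default 3).
#' @param n_permutations NBS permutations in the pipeline run (default
#'   1000; [nbs()] called directly defaults to 5000).
#' @param nbs_states which states get edge-wise tests: `"top2"` (the two
#'   most occupied, the convention for sparse dwelling), `"all"`, or an
#'   integer vector.
#' @param with_graph,with_nbs,with_dynamics stage toggles.
#' @param seed master seed.
#' @return a `dfc_report`: list with `config`, `elbow` (NULL when `k`
#'   fixed), `states` (a `state_set`), `dynamics`, `dynamics_tests`,
#'   `graph`, `nbs` (list of `nbs_result` keyed by
#'   `state<k>:<groupA>-<groupB>`), `log` (character vector of stage
#'   notes).
#' @export
#' @examples
#' \donttest{
#' spec <- mci_like_cohort_spec(n_per_group = c(NC = 4, eMCI = 4, lMCI = 4),
#'                              n_regions = 12, n_timepoints = 80, seed = 3)
#' rep <- run_pipeline(generate_cohort(spec), k = 4, with_nbs = FALSE,
#'                     n_restarts = 10, seed = 3)
#' rep$states$state_means
#' }
run_pipeline <- function(subjects, window_seconds = 30, step_tr = 1,
                         k = "auto", k_range = 2:10, n_exemplars = 7,
                         metric = "manhattan", n_restarts = 50, tau = 0.3,
                         nbs_threshold = 3, n_permutations = 1000,
                         nbs_states = "top2", with_graph = TRUE,
                         with_nbs = TRUE, with_dynamics = TRUE, seed = 1) {
  if (is.list(subjects) && !is.null(subjects$subjects)) {
    subjects <- subjects$subjects
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  config <- list(window_seconds = window_seconds, step_tr = step_tr, k = k,
                 k_range = k_range, n_exemplars = n_exemplars,
                 metric = metric, n_restarts = n_restarts, tau = tau,
                 nbs_threshold = nbs_threshold,
                 n_permutations = n_permutations, seed = seed)

  cohort <- lapply(subjects, build_windowed_fc,
                   window_seconds = window_seconds, step_tr = step_tr)
  note("windows: %d subjects, %d windows each (w = %d TRs, step %d)",
       length(cohort), length(cohort[[1]]$matrices),
       cohort[[1]]$window_length_tr, step_tr)

  elbow <- NULL
  if (identical(k, "auto")) {
    exemplars <- do.call(rbind, lapply(cohort, function(w) {
      select_exemplars(w, min(n_exemplars, length(w$matrices)))$features
    }))
    elbow <- elbow_select_k(exemplars, k_range = k_range, metric = metric,
                            seed = split_seed(seed, 61))
    k <- attr(elbow, "chosen_k")
    note("elbow: chose k = %d over k in [%d, %d]", k, min(k_range),
         max(k_range))
  }
  k <- as.integer(k)

  states <- two_stage_cluster(cohort, k, n_exemplars = n_exemplars,
                              metric = metric, seed = split_seed(seed, 62),
                              n_restarts = n_restarts)
  note("cluster: state means %s; occupancy %s",
       paste(sprintf("%.3f", states$state_means), collapse = "/"),
       paste(sprintf("%.3f", states$occupancy), collapse = "/"))

  dynamics <- NULL
  dynamics_tests <- NULL
  if (with_dynamics) {
    dynamics <- compute_dynamics(states)
    groups <- unique(dynamics$per_subject$group)
    if (length(groups) >= 2 &&
        all(table(dynamics$per_subject$group) >= 2)) {
      dynamics_tests <- compare_dynamics(dynamics)
    } else {
      note("dynamics: fewer than two groups with n >= 2, tests skipped")
    }
  }

  graph <- NULL
  if (with_graph) {
    graph <- state_graph_metrics(states, tau = tau,
                                 seed = split_seed(seed, 63))
  }

  nbs_results <- list()
  if (with_nbs) {
    target_states <- if (identical(nbs_states, "top2")) {
      head(order(-states$occupancy), 2)
    } else if (identical(nbs_states, "all")) seq_len(k) else
      as.integer(nbs_states)
    groups <- unique(vapply(cohort, function(w) w$group, ""))
    pairs <- if (length(groups) >= 2) combn(sort(groups), 2,
                                            simplify = FALSE) else list()
    for (s in target_states) {
      fc <- subject_state_fc(cohort, states, s)
      if (length(fc$excluded) > 0) {
        note("state %d: %d subjects excluded from edge tests (no windows)",
             s, length(fc$excluded))
      }
      for (pr in pairs) {
        ia <- fc$group == pr[1]
        ib <- fc$group == pr[2]
        if (sum(ia) < 2 || sum(ib) < 2) next
        key <- sprintf("state%d:%s-%s", s, pr[1], pr[2])
        nbs_results[[key]] <- nbs(
          fc$features[ia, , drop = FALSE], fc$features[ib, , drop = FALSE],
          primary_threshold = nbs_threshold,
          n_permutations = n_permutations,
          seed = split_seed(seed, 64, s, which(groups == pr[1])),
          region_labels = fc$region_labels)
      }
    }
  }

  structure(list(config = config, elbow = elbow, states = states,
                 dynamics = dynamics, dynamics_tests = dynamics_tests,
                 graph = graph, nbs = nbs_results, windows = cohort,
                 log = log),
            class = "dfc_report")
}

#' @export
print.dfc_report <- function(x, ...) {
  cat(sprintf("<dfc_report> %d states, window %gs, seed %d\n",
              x$states$k, x$config$window_seconds, x$config$seed))
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

#' Window-length sensitivity sweep
#'
#' Re-runs the windowing and state-extraction stages at several window
#' lengths and summarizes how the chosen number of states and the state
#' means vary — states extracted by this pipeline family should be
#' robust to the window length within the customary 30-60 s range.
#'
#' @param subjects as in [run_pipeline()].
#' @param window_seconds vector of window lengths (default
#'   `c(30, 40, 50, 60)`).
#' @param ... forwarded to [run_pipeline()] (graph/NBS/dynamics stages
#'   are disabled; the sweep concerns state extraction).
#' @param seed master seed (shared across lengths so differences reflect
#'   the window length only).
#' @return list with `reports` (one reduced `dfc_report` per length) and
#'   `summary` tibble (window_seconds, chosen_k, one row per state with
#'   its mean and occupancy).
#' @export
run_window_sweep <- function(subjects, window_seconds = c(30, 40, 50, 60),
                             ..., seed = 1) {
  reports <- lapply(window_seconds, function(ws) {
    run_pipeline(subjects, window_seconds = ws, ..., with_graph = FALSE,
                 with_nbs = FALSE, with_dynamics = FALSE, seed = seed)
  })
  names(reports) <- paste0(window_seconds, "s")
  summary <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    st <- reports[[i]]$states
    tibble::tibble(window_seconds = window_seconds[i], chosen_k = st$k,
                   state = seq_len(st$k), state_mean = st$state_means,
                   occupancy = st$occupancy)
  }))
  list(reports = reports, summary = summary)
}
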