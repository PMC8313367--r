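#' Write and read ROI time series as tab-delimited text
#'
#' The on-disk format is a plain TSV with one header row of region labels
#' and L rows of M signal values — the interchange format every stage of
#' the pipeline reads.
#'
#' @param ts a [roi_timeseries()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  df <- tibble::as_tibble(as.data.frame(ts$data))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @param subject_id,group,tr_seconds metadata not carried by the TSV.
#' @export
read_roi_timeseries <- function(path, subject_id = NULL,
                                group = NA_character_, tr_seconds = 2) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  roi_timeseries(as.matrix(df),
                 subject_id = subject_id %||%
                   sub("\\.tsv$", "", basename(path)),
                 group = group, tr_seconds = tr_seconds,
                 region_labels = colnames(df))
}

#' Write a generated cohort to a directory
#'
#' One TSV per subject, a two-column manifest (`subject_id`, `group`)
#' and the ground truth (planted labels, transition matrices, state
#' covariances) as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$subjects) {
    write_roi_timeseries(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  }
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  truth <- cohort$truth
  json <- list(labels = truth$labels,
               transition_matrices = truth$transition_matrices,
               state_covariances = lapply(truth$state_covariances,
                                          function(s) s$cov),
               mean_fc_levels = truth$spec$mean_fc_levels,
               tr_seconds = truth$spec$tr_seconds,
               noise_sd = truth$spec$noise_sd,
               seed = truth$spec$seed)
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory with per-subject TSVs and `manifest.tsv`.
#' @param tr_seconds repetition time of the series.
#' @return list with `subjects` and `manifest` (ground truth, if present,
#'   under `truth_file`).
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    read_roi_timeseries(file.path(dir, paste0(manifest$subject_id[i], ".tsv")),
                        subject_id = manifest$subject_id[i],
                        group = manifest$group[i], tr_seconds = tr_seconds)
  })
  tf <- file.path(dir, "ground_truth.json")
  list(subjects = subjects, manifest = manifest,
       truth_file = if (file.exists(tf)) tf else NULL)
}

#' Write a state set as delimited matrices plus JSON metadata
#'
#' @param state_set a `state_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_state_set <- function(state_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(state_set$k)) {
    readr::write_tsv(tibble::as_tibble(as.data.frame(state_set$states[[i]])),
                     file.path(dir, sprintf("state_%d.tsv", i)))
  }
  readr::write_tsv(state_set$assignments, file.path(dir, "assignments.tsv"))
  meta <- list(k = state_set$k, state_means = state_set$state_means,
               occupancy = state_set$occupancy, metric = state_set$metric,
               seed = state_set$seed,
               stage1_inertia = state_set$stage1$inertia,
               stage2_inertia = state_set$stage2$inertia)
  jsonlite::write_json(meta, file.path(dir, "states.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a machine-readable pipeline report
#'
#' Serializes the headline quantities of a [run_pipeline()] report —
#' chosen k, state means and occupancy, dynamics group tests, global
#' graph indicators and NBS component p-values — as JSON.
#'
#' @param report a `dfc_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  st <- report$states
  out <- list(
    config = report$config[c("window_seconds", "step_tr", "n_exemplars",
                             "metric", "tau", "seed")],
    k = st$k,
    state_means = st$state_means,
    occupancy = st$occupancy,
    dynamics_tests = report$dynamics_tests,
    global_metrics = if (!is.null(report$graph))
      report$graph$global_metrics else NULL,
    nbs = lapply(report$nbs, function(r) r$components),
    log = report$log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
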