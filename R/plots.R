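#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an elbow curve
#'
#' Intra/inter distance ratio against the candidate number of states,
#' with the chosen bend highlighted.
#'
#' @param object an `elbow_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.elbow_curve <- function(object, ...) {
  chosen <- attr(object, "chosen_k")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of states k",
                  y = "intra / inter cluster distance ratio",
                  title = sprintf("Elbow rule: k = %d", chosen)) +
    ggplot2::theme_minimal()
}

#' Heatmaps of the extracted state matrices
#'
#' @param object a `state_set`.
#' @param ... unused.
#' @return a ggplot faceted by state (ordered by descending mean).
#' @export
autoplot.state_set <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(seq_len(object$k), function(s) {
    m <- object$states[[s]]
    pairs <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
    tibble::tibble(
      state = sprintf("State %d (mean %.2f)", s, object$state_means[s]),
      i = pairs$i, j = pairs$j, z = m[cbind(pairs$i, pairs$j)])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "Fisher-Z") +
    ggplot2::facet_wrap(~state) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot temporal dynamics by group
#'
#' Occupancy fractions per state and transition counts, split by group.
#'
#' @param dynamics result of [compute_dynamics()].
#' @return a ggplot: state occupancy boxplots faceted by state with a
#'   transition-count panel.
#' @export
plot_state_dynamics <- function(dynamics) {
  occ <- dplyr::mutate(dynamics$per_state,
                       panel = sprintf("State %d occupancy", .data$state))
  tr <- dplyr::mutate(dynamics$per_subject, panel = "Transitions",
                      value = .data$n_transitions)
  df <- dplyr::bind_rows(
    dplyr::select(dplyr::rename(occ, value = "fraction"),
                  "group", "panel", "value"),
    dplyr::select(tr, "group", "panel", "value"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a subject's window-state sequence
#'
#' @param assignments assignment tibble or `state_set`.
#' @param subjects optional subject ids to show (default first six).
#' @return a ggplot of state label against window index per subject.
#' @export
plot_state_sequence <- function(assignments, subjects = NULL) {
  if (inherits(assignments, "state_set")) assignments <- assignments$assignments
  ids <- subjects %||% head(unique(assignments$subject_id), 6)
  df <- assignments[assignments$subject_id %in% ids, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_index, y = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~subject_id, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = sort(unique(df$state))) +
    ggplot2::labs(x = "window", y = "state") +
    ggplot2::theme_minimal()
}
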