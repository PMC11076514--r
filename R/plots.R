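# group colour convention used throughout the figures
.group_palette <- c(control = "#2ca02c", relative = "#1f77b4",
                    pwpp = "#d62728")

.join_group <- function(tbl, sessions) {
  dplyr::left_join(tbl,
                   dplyr::distinct(sessions, .data$subject_id, .data$group),
                   by = "subject_id")
}

#' Box plot of per-subject switch rates by group
#'
#' Median, 25-75% quartile box and 1.5 x IQR whiskers of per-subject switch
#' rates per group, with individual subjects overplotted.
#'
#' @param scores An `sfm_scores` object.
#' @param sessions The cohort `sessions` tibble (group labels).
#' @param rate Which column of the subject table to plot (default
#'   `mean_rate`, switches/s in the bi-stable task).
#' @param included_only Drop excluded sessions (default TRUE).
#' @return A ggplot object.
#' @export
plot_switch_rates <- function(scores, sessions, rate = "mean_rate",
                              included_only = TRUE) {
  d <- .join_group(scores$subjects, sessions) |>
    dplyr::filter(.data$session == 1)
  if (included_only) d <- dplyr::filter(d, .data$included)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[rate]],
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 3, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, colour = "grey40", size = 0.8) +
    ggplot2::scale_fill_manual(values = .group_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "switch rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Normalized percept-duration histograms by group
#'
#' @param scores An `sfm_scores` object.
#' @param sessions Cohort `sessions` tibble.
#' @param block_type `"bistable"` (default) or `"real_switch"`.
#' @param bin_edges Histogram bin edges in seconds.
#' @return A ggplot object.
#' @export
plot_duration_histograms <- function(scores, sessions,
                                     block_type = "bistable",
                                     bin_edges = seq(0, 40, by = 2)) {
  d <- .join_group(scores$durations, sessions) |>
    dplyr::filter(.data$block_type == !!block_type, .data$session == 1)
  h <- duration_histogram(d, duration, group, bin_edges = bin_edges)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lo, y = .data$proportion,
                                  colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .group_palette) +
    ggplot2::labs(x = "percept duration (s)", y = "proportion of responses",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Session-1 vs session-2 switch-rate scatter
#'
#' Test-retest scatter of per-subject switch rates for subjects with two
#' sessions, on the identity line.
#'
#' @inheritParams plot_switch_rates
#' @return A ggplot object.
#' @export
plot_retest <- function(scores, sessions, rate = "mean_rate") {
  d <- .join_group(scores$subjects, sessions) |>
    dplyr::filter(.data$included) |>
    dplyr::select("subject_id", "group", "session",
                  value = dplyr::all_of(rate)) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value",
                       names_prefix = "session_") |>
    dplyr::filter(!is.na(.data$session_1), !is.na(.data$session_2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$session_1, y = .data$session_2,
                                  colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = .group_palette) +
    ggplot2::labs(x = "session 1 switch rate (Hz)",
                  y = "session 2 switch rate (Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Real-switch accuracy by group with the inclusion cutoff
#'
#' @inheritParams plot_switch_rates
#' @return A ggplot object.
#' @export
plot_accuracy <- function(scores, sessions) {
  d <- .join_group(scores$subjects, sessions) |>
    dplyr::filter(.data$session == 1, !is.na(.data$accuracy))
  cutoff <- (scores$min_correct - 1) / 11
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$accuracy,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2) +
    ggplot2::scale_fill_manual(values = .group_palette, guide = "none") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "real-switch detection accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_switch_rates `autoplot()` method: switch-rate box plot
#'   for a scored cohort (requires the sessions table as `sessions =`).
#' @param object An `sfm_scores` object.
#' @param ... Passed on to [plot_switch_rates()].
#' @export
autoplot.sfm_scores <- function(object, sessions, ...) {
  plot_switch_rates(object, sessions, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
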