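#' Boxplots of the six similarity metrics by outcome class
#'
#' @param profiles Output of [similarity_profiles()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(profiles,
                              cols = c("ed", "md", "dtw", "xcrd", "cc", "cs"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "baseline-vs-session value",
                  title = "Similarity/distance profiles by outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Session-wise group means of a metric over the training course
#'
#' The adherence-trend view: the mean of one metric per training session and
#' outcome group.
#'
#' @param cohort An `mfc_cohort`.
#' @param metric One of `"ed"`, `"md"`, `"dtw"`, `"xcrd"`, `"cc"`, `"cs"`.
#' @param config An [mfc_config()].
#' @return A ggplot object.
#' @export
plot_session_trend <- function(cohort, metric = "cs", config = mfc_config()) {
  prof <- similarity_profiles(cohort, sessions = training_sessions(),
                              config = config)
  trend <- prof |>
    dplyr::mutate(session_no = as.integer(sub("train_", "", .data$session))) |>
    dplyr::group_by(.data$session_no, .data$label) |>
    dplyr::summarise(mean_value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(trend, ggplot2::aes(x = .data$session_no,
                                      y = .data$mean_value,
                                      colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "training session", y = paste("mean", metric),
                  title = "Session-wise adherence trend") +
    ggplot2::theme_minimal()
}

#' Plot GPS_MFC trajectories
#'
#' @param object A `gps_trajectory` tibble ([gps_trajectories()]).
#' @param ... Unused.
#' @return A ggplot object; one line per patient, coloured by outcome.
#' @method autoplot gps_trajectory
#' @export
autoplot.gps_trajectory <- function(object, ...) {
  ggplot2::ggplot(object[object$available, ],
                  ggplot2::aes(x = .data$session_no, y = .data$gps,
                               group = .data$patient_id,
                               colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "training session", y = "GPS_MFC",
                  title = "Per-patient adherence trajectories") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of inter-session GPS_MFC variation
#'
#' Positive bars (improvement under the dissimilarity convention) in red,
#' negative in blue; intervals zeroed by data loss are blank.
#'
#' @param deltas Output of [delta_gps()].
#' @return A ggplot object faceted by patient.
#' @export
plot_delta_gps <- function(deltas) {
  d <- dplyr::mutate(deltas,
                     direction = dplyr::case_when(
                       .data$zeroed_by_missing ~ "missing",
                       .data$delta >= 0 ~ "increment",
                       TRUE ~ "decrement"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$delta,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~patient_id) +
    ggplot2::scale_fill_manual(values = c(increment = "firebrick",
                                          decrement = "steelblue",
                                          missing = "grey80")) +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "session interval (i → i+1)",
                  y = expression(Delta * GPS[MFC]),
                  title = "Inter-session adherence variation") +
    ggplot2::theme_minimal()
}
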