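#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a physiological channel
#'
#' @param object A [channel()].
#' @param max_points Channels longer than this are thinned for drawing.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.physio_channel <- function(object, max_points = 20000, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points) df <- df[seq(1L, nrow(df), length.out = max_points), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s (%s)", channel_modality(object), channel_units(object)),
                  title = sprintf("%s channel, fs = %g Hz", channel_modality(object),
                                  channel_fs(object))) +
    ggplot2::theme_minimal()
}

#' Plot breath-onset detection over the smoothed respiration signal
#'
#' @param smoothed A `resp_smoothed` object.
#' @param events A `breath_events` object detected from it.
#' @return A ggplot with inhalation/exhalation onsets marked.
#' @export
plot_breath_detection <- function(smoothed, events) {
  ch <- smoothed$channel
  df <- tibble::as_tibble(ch)
  on <- tibble::tibble(
    time_s = c(events$inhalation_onsets_s, events$exhalation_onsets_s),
    type = rep(c("inhalation", "exhalation"),
               c(length(events$inhalation_onsets_s),
                 length(events$exhalation_onsets_s)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_vline(data = on,
                        ggplot2::aes(xintercept = .data$time_s, colour = .data$type),
                        alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "normalized respiration",
                  colour = "onset") +
    ggplot2::theme_minimal()
}

#' Plot a feature table as per-window trajectories
#'
#' @param features Feature tibble from [run_pipeline()].
#' @param measure One of `"BR"`, `"HR"`, `"EDA"`, `"HRV"`.
#' @return A ggplot of per-participant trajectories by stimulus group.
#' @export
plot_feature_trajectories <- function(features, measure = c("BR", "HR", "EDA", "HRV")) {
  measure <- match.arg(measure)
  long <- features_long(features, measure)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                     group = .data$participant,
                                     colour = .data$stim)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$stim), fun = mean,
                          geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "timepoint", y = measure, colour = "stimulus") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
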