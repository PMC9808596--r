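#' Plot segment-velocity distributions by context class
#'
#' Boxplots of segment average velocities per sensor and context class —
#' the visual validity check that action segments are faster than
#' task-free ones.
#'
#' @param segments classified per-segment velocities.
#' @return A ggplot object.
#' @export
plot_velocity_by_class <- function(segments) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$action_class,
                               y = .data$mean_velocity,
                               fill = .data$action_class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~sensor) +
    ggplot2::labs(x = NULL, y = "segment average velocity (m/s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-participant velocity over study days with trend lines
#'
#' Action-segment average velocities against study day for one sensor,
#' one panel per participant, with each participant's fitted regression
#' line overlaid.
#'
#' @param segments classified per-segment velocities.
#' @param sensor which sensor to show (`"head"`, `"left"`, `"right"`).
#' @return A ggplot object.
#' @export
plot_participant_velocity <- function(segments, sensor = "right") {
  dat <- segments[segments$sensor == sensor &
                    segments$action_class == "action", ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$study_day,
                                    y = .data$mean_velocity)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "firebrick") +
    ggplot2::facet_wrap(~participant_id, scales = "free_y") +
    ggplot2::labs(x = "study day",
                  y = sprintf("action-segment velocity, %s sensor (m/s)",
                              sensor)) +
    ggplot2::theme_minimal()
}

#' Plot peaks/minute distributions per participant, ordered by median
#'
#' @param stats per-segment statistics from [eda_segment_stats()].
#' @return A ggplot object.
#' @export
plot_peak_distributions <- function(stats) {
  ord <- arm_peak_summary(stats)
  stats$participant_id <- factor(stats$participant_id,
                                 levels = ord$participant_id)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$participant_id,
                                      y = .data$peaks_per_minute,
                                      fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "participant (ascending median)",
                  y = "phasic peaks / minute") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot weekly mean steps per arm
#'
#' @param weekly output of [weekly_step_changes()].
#' @return A ggplot object.
#' @export
plot_weekly_steps <- function(weekly) {
  ggplot2::ggplot(weekly,
                  ggplot2::aes(x = factor(.data$study_week),
                               y = .data$mean_daily_steps,
                               fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "study week", y = "mean daily steps") +
    ggplot2::theme_minimal()
}
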