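#' Weekly step changes from baseline week
#'
#' Aggregates daily step counts to study weeks (`ceiling(study_day / 7)`,
#' aligned to randomization, not calendar weeks) and expresses each
#' participant-week mean as a change from that participant's week-1 mean.
#' Week means use the days actually present; participants with no week-1
#' data have no baseline and are excluded with a warning.
#'
#' @param days activity tibble ([read_activity()] /
#'   [simulate_activity()] format).
#' @return A tibble with columns `participant_id`, `arm`, `study_week`,
#'   `n_days`, `mean_daily_steps`, `change_from_baseline`; week-1 change
#'   is exactly 0 for every included participant.
#' @export
weekly_step_changes <- function(days) {
  weekly <- days %>%
    mutate(study_week = as.integer(ceiling(.data$study_day / 7))) %>%
    group_by(.data$participant_id, .data$arm, .data$study_week) %>%
    summarise(n_days = n(), mean_daily_steps = mean(.data$steps),
              .groups = "drop")
  baselines <- weekly %>%
    filter(.data$study_week == 1L) %>%
    select("participant_id", baseline = "mean_daily_steps")
  missing_baseline <- setdiff(unique(weekly$participant_id),
                              baselines$participant_id)
  if (length(missing_baseline) > 0L) {
    warning(length(missing_baseline),
            " participant(s) without week-1 data were excluded: ",
            paste(missing_baseline, collapse = ", "), call. = FALSE)
  }
  weekly %>%
    dplyr::inner_join(baselines, by = "participant_id") %>%
    mutate(change_from_baseline = .data$mean_daily_steps - .data$baseline) %>%
    select("participant_id", "arm", "study_week", "n_days",
           "mean_daily_steps", "change_from_baseline") %>%
    arrange(.data$participant_id, .data$study_week)
}

#' Per-participant step trends with an arm-level summary
#'
#' Stage one fits an ordinary least-squares line of daily steps on study
#' day for each participant (slope in steps/day per day); stage two
#' summarizes the slopes per arm (mean, sd, n) and tabulates all pairwise
#' between-arm mean differences. This two-stage scheme gives every
#' participant their own regression line and keeps the group contrast
#' fully explicit. Participants with fewer than two distinct days are
#' degenerate and excluded with a warning.
#'
#' @param days activity tibble.
#' @return A list with elements `slopes` (per participant:
#'   `participant_id`, `arm`, `slope`, `n_days`), `arm_summary` (per arm:
#'   `n`, `mean_slope`, `sd_slope`) and `arm_differences` (pairwise
#'   `mean_slope` differences, in steps/day per day).
#' @export
participant_step_trends <- function(days) {
  designs <- days %>%
    group_by(.data$participant_id, .data$arm) %>%
    summarise(n_days = n_distinct(.data$study_day), .groups = "drop")
  bad <- designs$n_days < 2L
  if (any(bad)) {
    warning(sum(bad), " participant(s) with < 2 distinct study days ",
            "were excluded from the trend fit", call. = FALSE)
  }
  keep <- designs[!bad, ]
  if (nrow(keep) == 0L) {
    stop("no participant has enough days for a trend fit", call. = FALSE)
  }
  slopes <- days %>%
    dplyr::semi_join(keep, by = "participant_id") %>%
    group_by(.data$participant_id, .data$arm) %>%
    summarise(
      slope = coef(lm(steps ~ study_day,
                      data = dplyr::pick(dplyr::everything())))[[2L]],
      n_days = n(), .groups = "drop")
  arm_summary <- slopes %>%
    group_by(.data$arm) %>%
    summarise(n = n(), mean_slope = mean(.data$slope),
              sd_slope = sd(.data$slope), .groups = "drop")
  if (nrow(arm_summary) >= 2L) {
    pairs <- utils::combn(arm_summary$arm, 2L, simplify = FALSE)
    arm_differences <- bind_rows(lapply(pairs, function(p) {
      tibble(arm_a = p[[1L]], arm_b = p[[2L]],
             mean_slope_diff =
               arm_summary$mean_slope[arm_summary$arm == p[[1L]]] -
               arm_summary$mean_slope[arm_summary$arm == p[[2L]]])
    }))
  } else {
    arm_differences <- tibble(arm_a = character(0), arm_b = character(0),
                              mean_slope_diff = numeric(0))
  }
  list(slopes = slopes, arm_summary = arm_summary,
       arm_differences = arm_differences)
}

#' Descriptive summary of heart rate and sleep
#'
#' Daily heart-rate means and sleep durations are aggregated per arm for
#' description only: the daytime-aggregated heart-rate export carries too
#' little precision for clinical analysis, so no model is fitted to it.
#'
#' @param days activity tibble.
#' @return A tibble per arm: n days, mean/sd of heart rate and sleep
#'   minutes over non-missing days.
#' @export
activity_descriptives <- function(days) {
  days %>%
    group_by(.data$arm) %>%
    summarise(
      n_days = n(),
      heart_rate_mean = mean(.data$heart_rate_mean, na.rm = TRUE),
      heart_rate_sd = sd(.data$heart_rate_mean, na.rm = TRUE),
      sleep_minutes_mean = mean(.data$sleep_minutes, na.rm = TRUE),
      sleep_minutes_sd = sd(.data$sleep_minutes, na.rm = TRUE),
      .groups = "drop")
}
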