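#' Per-timepoint velocities of one motion segment
#'
#' Converts the tri-axial position samples of one segment into speeds:
#' for each consecutive sample pair,
#' `v = sqrt(dx^2 + dy^2 + dz^2) / dt` (m/s). The first sample yields no
#' point. Pairs whose time difference is non-positive or exceeds
#' `gap_threshold` are skipped (a long gap usually marks a segment that
#' did not end cleanly, and one huge `dt` would poison the segment mean);
#' if a `velocity_cap` is set, points above it are dropped (non-natural
#' movement such as a dropped controller). Both counts are returned as
#' attributes, never silently.
#'
#' @param segment tibble of samples for one segment, with columns `t`,
#'   `x`, `y`, `z`, in recording order.
#' @param gap_threshold maximum usable `dt` in seconds (default 0.5, vs
#'   a nominal 1/30 s sampling interval).
#' @param velocity_cap optional speed ceiling in m/s (`NULL` = no cap).
#' @return A tibble with columns `t` (timestamp of the later sample) and
#'   `v` (m/s), with attributes `n_skipped_gaps` and `n_dropped_cap`. A
#'   segment with fewer than two usable samples returns zero rows
#'   (insufficient data; the caller excludes the segment).
#' @export
point_velocities <- function(segment, gap_threshold = 0.5,
                             velocity_cap = NULL) {
  n <- nrow(segment)
  empty <- tibble(t = numeric(0), v = numeric(0))
  if (n < 2L) {
    attr(empty, "n_skipped_gaps") <- 0L
    attr(empty, "n_dropped_cap") <- 0L
    return(empty)
  }
  dt <- diff(segment$t)
  dd <- sqrt(diff(segment$x)^2 + diff(segment$y)^2 + diff(segment$z)^2)
  usable <- dt > 0 & dt <= gap_threshold
  v <- dd[usable] / dt[usable]
  t <- segment$t[-1L][usable]
  n_dropped_cap <- 0L
  if (!is.null(velocity_cap)) {
    over <- v > velocity_cap
    n_dropped_cap <- sum(over)
    v <- v[!over]
    t <- t[!over]
  }
  out <- tibble(t = t, v = v)
  attr(out, "n_skipped_gaps") <- sum(!usable)
  attr(out, "n_dropped_cap") <- n_dropped_cap
  out
}

#' Average velocity of one segment
#'
#' Aggregates per-timepoint speeds to the segment's average velocity, the
#' quantity used to assess how quickly a participant completed the
#' segment's task. Duration is taken from the segment's first and last
#' sample timestamps (robust to dropped samples), not from the sample
#' count and nominal rate.
#'
#' @param points velocity points from [point_velocities()].
#' @param segment the segment's sample tibble (for identity fields and
#'   duration; columns `segment_id`, `sensor`, `study_day`, `t` and
#'   optionally `tag`).
#' @return A one-row tibble (`segment_id`, `sensor`, `study_day`, `tag`,
#'   `mean_velocity`, `duration`, `n_points`), or `NULL` when there are
#'   no velocity points (insufficient data).
#' @export
segment_mean_velocity <- function(points, segment) {
  if (nrow(points) == 0L) {
    return(NULL)
  }
  tibble(
    segment_id = segment$segment_id[[1L]],
    sensor = segment$sensor[[1L]],
    study_day = segment$study_day[[1L]],
    tag = if ("tag" %in% names(segment)) segment$tag[[1L]] else NA_character_,
    mean_velocity = mean(points$v),
    duration = max(segment$t) - min(segment$t),
    n_points = nrow(points)
  )
}

#' Per-segment average velocities for a whole sample table
#'
#' Vectorized application of [point_velocities()] +
#' [segment_mean_velocity()] over every segment of a (possibly
#' multi-participant) motion sample table. Segments with fewer than two
#' usable samples are excluded and counted.
#'
#' @param samples motion sample tibble ([read_motion_records()] /
#'   [simulate_motion()] format), ordered within segments.
#' @inheritParams point_velocities
#' @return A tibble with one row per segment (`participant_id`, `sensor`,
#'   `study_day`, `segment_id`, `tag`, `t_start`, `mean_velocity`,
#'   `duration`, `n_points`) and attributes `n_skipped_gaps`,
#'   `n_dropped_cap`, `n_excluded_segments`.
#' @export
segment_velocities <- function(samples, gap_threshold = 0.5,
                               velocity_cap = NULL) {
  n <- nrow(samples)
  if (n == 0L) stop("no motion samples", call. = FALSE)
  same_seg <- samples$segment_id[-1L] == samples$segment_id[-n]
  dt <- diff(samples$t)
  dd <- sqrt(diff(samples$x)^2 + diff(samples$y)^2 + diff(samples$z)^2)
  usable <- same_seg & dt > 0 & dt <= gap_threshold
  n_skipped_gaps <- sum(same_seg & !(dt > 0 & dt <= gap_threshold))
  v <- dd / dt
  keep <- usable
  n_dropped_cap <- 0L
  if (!is.null(velocity_cap)) {
    over <- usable & v > velocity_cap
    n_dropped_cap <- sum(over)
    keep <- usable & !over
  }
  pair_seg <- samples$segment_id[-1L]
  vt <- tibble(segment_id = pair_seg[keep], v = v[keep])
  per_point <- vt %>%
    group_by(.data$segment_id) %>%
    summarise(mean_velocity = mean(.data$v), n_points = n(),
              .groups = "drop")
  meta <- samples %>%
    group_by(.data$participant_id, .data$sensor, .data$study_day,
             .data$segment_id, .data$tag) %>%
    summarise(t_start = min(.data$t),
              duration = max(.data$t) - min(.data$t), .groups = "drop")
  out <- meta %>%
    left_join(per_point, by = "segment_id")
  n_excluded <- sum(is.na(out$mean_velocity))
  out <- out %>%
    filter(!is.na(.data$mean_velocity)) %>%
    arrange(.data$participant_id, .data$sensor, .data$study_day,
            .data$t_start) %>%
    select("participant_id", "sensor", "study_day", "segment_id", "tag",
           "t_start", "mean_velocity", "duration", "n_points")
  attr(out, "n_skipped_gaps") <- n_skipped_gaps
  attr(out, "n_dropped_cap") <- n_dropped_cap
  attr(out, "n_excluded_segments") <- n_excluded
  out
}

#' Classify segment context from metadata tags
#'
#' Sets each segment's `action_class`. Segments whose tag is in
#' `action_tags` are `action`; task-free segments are classified by their
#' position within the participant x sensor x study day: before the
#' day's first action segment `no_action_start_of_day`, after its last
#' `no_action_end_of_day`, otherwise `no_action_between`. A day with no
#' action segment at all labels every segment start-of-day and emits a
#' warning.
#'
#' @param segments per-segment tibble (e.g. from [segment_velocities()])
#'   with columns `participant_id`, `sensor`, `study_day`, `tag` and
#'   `t_start` (or already day-ordered rows).
#' @param action_tags character vector of metadata tags that count as
#'   action.
#' @return `segments` with an `action_class` column.
#' @export
classify_segment_context <- function(segments, action_tags = "task") {
  if (nrow(segments) == 0L) {
    segments$action_class <- character(0)
    return(segments)
  }
  if ("t_start" %in% names(segments)) {
    segments <- segments %>%
      arrange(.data$participant_id, .data$sensor, .data$study_day,
              .data$t_start)
  }
  is_action <- segments$tag %in% action_tags
  key <- paste(segments$participant_id, segments$sensor,
               segments$study_day, sep = "\r")
  cls <- character(nrow(segments))
  dayless <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    act <- is_action[idx]
    if (!any(act)) {
      cls[idx] <- "no_action_start_of_day"
      dayless <- c(dayless, k)
      next
    }
    first_a <- min(which(act))
    last_a <- max(which(act))
    pos <- seq_along(idx)
    cls[idx] <- dplyr::case_when(
      act ~ "action",
      pos < first_a ~ "no_action_start_of_day",
      pos > last_a ~ "no_action_end_of_day",
      TRUE ~ "no_action_between"
    )
  }
  if (length(dayless) > 0L) {
    warning(length(dayless),
            " participant-day(s) contain no action segment; ",
            "all their segments were labeled start-of-day",
            call. = FALSE)
  }
  segments$action_class <- cls
  segments
}

#' Per-participant velocity change over the study
#'
#' Estimates each participant's movement improvement per sensor:
#' ordinary least squares of action-segment average velocity on the
#' 1-based VR study-day ordinal (one observation per action segment),
#' giving a slope in m/s per study day, then the study-scale change
#' `slope * vr_study_day_count`. Only action segments enter the
#' regression; the day count is the number of distinct study days in the
#' participant's full series. Participant x sensor combinations with
#' fewer than two action segments or all observations on one day are
#' degenerate and excluded with a warning.
#'
#' @param segments classified per-segment velocities
#'   ([classify_segment_context()] output).
#' @return A tibble with columns `participant_id`, `sensor`, `slope`
#'   (m/s per study day), `change` (m/s, `slope * vr_study_day_count`),
#'   `n_segments`, `vr_study_day_count`.
#' @export
fit_daily_slope <- function(segments) {
  if (!"action_class" %in% names(segments)) {
    stop("segments must be classified first (see classify_segment_context)",
         call. = FALSE)
  }
  day_counts <- segments %>%
    group_by(.data$participant_id) %>%
    summarise(vr_study_day_count = n_distinct(.data$study_day),
              .groups = "drop")
  action <- segments %>% filter(.data$action_class == "action")
  groups <- action %>%
    group_by(.data$participant_id, .data$sensor) %>%
    summarise(n_segments = n(), n_days = n_distinct(.data$study_day),
              .groups = "drop")
  bad <- groups$n_segments < 2L | groups$n_days < 2L
  if (any(bad)) {
    warning(sum(bad), " participant-sensor series had a degenerate design ",
            "(< 2 action segments or a single study day) and were excluded",
            call. = FALSE)
  }
  keep <- groups[!bad, c("participant_id", "sensor", "n_segments")]
  if (nrow(keep) == 0L) {
    stop("no participant-sensor series with a usable regression design",
         call. = FALSE)
  }
  fits <- action %>%
    dplyr::semi_join(keep, by = c("participant_id", "sensor")) %>%
    group_by(.data$participant_id, .data$sensor) %>%
    summarise(
      slope = coef(lm(mean_velocity ~ study_day,
                      data = dplyr::pick(dplyr::everything())))[[2L]],
      n_segments = n(), .groups = "drop")
  fits %>%
    left_join(day_counts, by = "participant_id") %>%
    mutate(change = .data$slope * .data$vr_study_day_count) %>%
    select("participant_id", "sensor", "slope", "change", "n_segments",
           "vr_study_day_count")
}

#' Segment-velocity distributions by context class
#'
#' The segmentation validity check: per sensor and context class, the
#' count, mean and quartiles of segment average velocities. Action
#' segments are expected to be faster on average than task-free ones;
#' classes absent from the data are reported with zero count.
#'
#' @param segments classified per-segment velocities.
#' @return A tibble with columns `sensor`, `action_class`, `n`, `mean`,
#'   `q25`, `median`, `q75`.
#' @export
velocity_by_class_summary <- function(segments) {
  out <- segments %>%
    group_by(.data$sensor, .data$action_class) %>%
    summarise(n = n(),
              mean = mean(.data$mean_velocity),
              q25 = unname(stats::quantile(.data$mean_velocity, 0.25)),
              median = median(.data$mean_velocity),
              q75 = unname(stats::quantile(.data$mean_velocity, 0.75)),
              .groups = "drop")
  tidyr::complete(out,
                  sensor = unique(segments$sensor),
                  action_class = ACTION_CLASSES,
                  fill = list(n = 0L)) %>%
    arrange(.data$sensor, match(.data$action_class, ACTION_CLASSES))
}
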