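#' First differences of an electrodermal segment
#'
#' Isolates the phasic (fast) component of a skin-conductance segment by
#' first differencing: `delta_i = value_i - value_(i-1)`, keeping the
#' later sample's timestamp. Differencing removes the tonic level and
#' turns any linear tonic trend into a constant, making the series
#' stationary enough for a robust band to be meaningful.
#'
#' @param segment tibble with columns `t` (seconds) and `value`
#'   (microsiemens) for one segment, in time order.
#' @return A tibble with columns `t` and `delta`, one row fewer than the
#'   input; zero rows when the segment has fewer than two samples
#'   (insufficient data).
#' @export
phasic_differences <- function(segment) {
  if (nrow(segment) < 2L) {
    return(tibble(t = numeric(0), delta = numeric(0)))
  }
  tibble(t = segment$t[-1L], delta = diff(segment$value))
}

#' Median absolute deviation (unscaled)
#'
#' `MAD = median(|x_i - median(x)|)`, the robust spread measure used to
#' form the phasic peak band. No consistency constant is applied: the
#' band is defined directly in MAD units, not as a standard-deviation
#' estimate. Even-length medians use the midpoint convention.
#'
#' @param values non-empty numeric vector.
#' @return The MAD as a single number.
#' @export
eda_mad <- function(values) {
  if (length(values) == 0L) {
    stop("MAD of an empty vector is undefined", call. = FALSE)
  }
  stats::mad(values, constant = 1)
}

#' Count phasic peaks in a differenced segment
#'
#' Peaks are differenced values strictly above the band
#' `median(delta) + 2 * MAD(delta)`, computed within the segment; the
#' count is normalized by segment duration to peaks/minute. When the MAD
#' is zero the band degenerates to the median alone; the segment is still
#' counted but flagged (`degenerate_band`). An alternative band of
#' `2 * MAD` without the median anchor is available via
#' `band = "mad_only"`.
#'
#' @param phasic differenced segment from [phasic_differences()]
#'   (non-empty).
#' @param duration_minutes segment duration in minutes (> 0), measured
#'   from timestamps.
#' @param band `"median_anchored"` (default): threshold
#'   `median + 2 * MAD`; `"mad_only"`: threshold `2 * MAD`.
#' @return A one-row tibble: `median_delta`, `mad_delta`, `threshold`,
#'   `peak_count`, `duration_minutes`, `peaks_per_minute`,
#'   `degenerate_band`.
#' @export
count_peaks <- function(phasic, duration_minutes,
                        band = c("median_anchored", "mad_only")) {
  band <- match.arg(band)
  if (nrow(phasic) == 0L) {
    stop("cannot count peaks of an empty differenced segment",
         call. = FALSE)
  }
  if (!is.finite(duration_minutes) || duration_minutes <= 0) {
    stop("segment duration must be positive", call. = FALSE)
  }
  d <- phasic$delta
  med <- median(d)
  mad <- eda_mad(d)
  threshold <- switch(band,
                      median_anchored = med + 2 * mad,
                      mad_only = 2 * mad)
  peak_count <- sum(d > threshold)
  tibble(
    median_delta = med, mad_delta = mad, threshold = threshold,
    peak_count = as.integer(peak_count),
    duration_minutes = duration_minutes,
    peaks_per_minute = peak_count / duration_minutes,
    degenerate_band = mad == 0
  )
}

#' Remove start-of-day segments from active-arm EDA
#'
#' Active-arm (DTxP) sessions begin with preparation time before the
#' first task; those start-of-day segments are removed so that the active
#' phase is compared against the sham arm, whose sessions are assumed to
#' be entirely task-free. Sham-arm series pass through unchanged.
#'
#' @param eda EDA tibble ([read_eda()] / [simulate_eda()] format) with
#'   `arm` and `action_class` columns.
#' @return The filtered tibble, with attribute `n_removed_segments`.
#' @export
filter_start_of_day <- function(eda) {
  drop <- eda$arm == "DTxP" & eda$action_class == "no_action_start_of_day"
  removed <- length(unique(eda$segment_id[drop]))
  out <- eda[!drop, , drop = FALSE]
  attr(out, "n_removed_segments") <- removed
  out
}

#' Per-segment phasic peak statistics for an EDA table
#'
#' Applies [phasic_differences()] and [count_peaks()] to every segment.
#' Segments with fewer than two samples or zero duration are excluded and
#' counted.
#'
#' @param eda EDA tibble with columns `participant_id`, `arm`,
#'   `segment_id`, `t`, `value`.
#' @inheritParams count_peaks
#' @return A tibble with one row per usable segment (`participant_id`,
#'   `arm`, `segment_id`, plus the [count_peaks()] columns) and attribute
#'   `n_excluded_segments`.
#' @export
eda_segment_stats <- function(eda, band = c("median_anchored", "mad_only")) {
  band <- match.arg(band)
  segs <- split(eda, eda$segment_id)
  rows <- vector("list", length(segs))
  excluded <- 0L
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    dur_min <- (max(seg$t) - min(seg$t)) / 60
    ph <- phasic_differences(seg)
    if (nrow(ph) == 0L || dur_min <= 0) {
      excluded <- excluded + 1L
      next
    }
    stats <- count_peaks(ph, dur_min, band = band)
    rows[[i]] <- dplyr::bind_cols(
      tibble(participant_id = seg$participant_id[[1L]],
             arm = seg$arm[[1L]], segment_id = seg$segment_id[[1L]]),
      stats
    )
  }
  out <- bind_rows(rows)
  out <- out %>% arrange(.data$participant_id, .data$segment_id)
  attr(out, "n_excluded_segments") <- excluded
  out
}

#' Per-participant peaks/minute distributions, ordered by median
#'
#' Summarizes each participant's distribution of segment peaks/minute
#' (n, quartiles, median), sorted ascending by median with ties broken by
#' participant id — the ordering used to compare active and sham arms
#' visually.
#'
#' @param stats per-segment statistics from [eda_segment_stats()].
#' @return A tibble with columns `participant_id`, `arm`, `n_segments`,
#'   `q25`, `median`, `q75`, sorted by `median` then `participant_id`.
#' @export
arm_peak_summary <- function(stats) {
  if (nrow(stats) == 0L) {
    stop("no segment statistics to summarise", call. = FALSE)
  }
  stats %>%
    group_by(.data$participant_id, .data$arm) %>%
    summarise(n_segments = n(),
              q25 = unname(stats::quantile(.data$peaks_per_minute, 0.25)),
              median = median(.data$peaks_per_minute),
              q75 = unname(stats::quantile(.data$peaks_per_minute, 0.75)),
              .groups = "drop") %>%
    arrange(.data$median, .data$participant_id)
}
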