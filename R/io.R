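#' Read a raw motion record stream
#'
#' Parses a line-delimited text stream of motion samples into a tidy sample
#' table. Each record is one comma-separated line with the header fields
#' `participant`, `sensor`, `study_day`, `tag`, `t`, `x`, `y`, `z`:
#' one position sample of one sensor (`head`, `left` or `right`) at `t`
#' seconds since session start, in meters in the device's world frame, plus
#' the software metadata tag active when the sample was recorded.
#'
#' Samples are grouped into motion segments: within each
#' participant x sensor x study day, a segment is a maximal run of
#' consecutive records sharing one metadata tag. Streams may carry an
#' optional `segment` field (as written by [write_motion_records()]); when
#' present it defines the grouping directly, which keeps consecutive
#' same-tag segments apart. Record order is preserved within a segment;
#' nothing is reordered.
#'
#' Malformed records (non-numeric or missing coordinate or timestamp, or a
#' missing sensor label) are skipped and counted, not fatal; the count is
#' returned in the `n_skipped` attribute. A line that cannot be split into
#' the header's fields is a format error and aborts with the line number.
#'
#' @param source path to the record-stream file.
#' @return A tibble with columns `participant_id`, `sensor`, `study_day`,
#'   `segment_id`, `tag`, `t`, `x`, `y`, `z`, ordered as in the stream,
#'   with attribute `n_skipped` (count of skipped records).
#' @seealso [write_motion_records()] for the inverse.
#' @export
read_motion_records <- function(source) {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("empty motion record stream: ", source, call. = FALSE)
  }
  header <- trimws(strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]])
  required <- c("participant", "sensor", "study_day", "tag", "t", "x", "y", "z")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop("motion stream header lacks field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1L]
  fields <- strsplit(body, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  bad_shape <- which(n_fields != length(header))
  if (length(bad_shape) > 0L) {
    stop("unreadable motion record at line ", bad_shape[[1L]] + 1L,
         ": expected ", length(header), " fields, found ",
         n_fields[[bad_shape[[1L]]]], call. = FALSE)
  }
  mat <- matrix(trimws(unlist(fields)), ncol = length(header), byrow = TRUE)
  colnames(mat) <- header
  num <- function(col) suppressWarnings(as.numeric(mat[, col]))
  raw <- tibble(
    participant_id = mat[, "participant"],
    sensor = mat[, "sensor"],
    study_day = num("study_day"),
    tag = mat[, "tag"],
    t = num("t"), x = num("x"), y = num("y"), z = num("z")
  )
  ok <- nzchar(raw$participant_id) &
    raw$sensor %in% SENSORS &
    is.finite(raw$study_day) & raw$study_day >= 1 &
    is.finite(raw$t) & is.finite(raw$x) & is.finite(raw$y) & is.finite(raw$z)
  n_skipped <- sum(!ok)
  samples <- raw[ok, , drop = FALSE]
  if (nrow(samples) == 0L) {
    stop("no valid motion records in ", source,
         " (", n_skipped, " skipped)", call. = FALSE)
  }
  samples$study_day <- as.integer(samples$study_day)
  if ("segment" %in% header) {
    samples$segment_id <- mat[ok, "segment"]
  } else {
    # a segment is a run of one tag within participant x sensor x day,
    # in stream order
    key <- paste(samples$participant_id, samples$sensor, samples$study_day,
                 sep = "\r")
    run_break <- c(TRUE, key[-1L] != key[-nrow(samples)] |
                     samples$tag[-1L] != samples$tag[-nrow(samples)])
    run_id <- cumsum(run_break)
    samples$segment_id <- sprintf("%s_%s_d%02d_s%03d",
                                  samples$participant_id, samples$sensor,
                                  samples$study_day,
                                  as.integer(stats::ave(run_id, key,
                                    FUN = function(r) match(r, unique(r)))))
  }
  samples <- samples[, c("participant_id", "sensor", "study_day",
                         "segment_id", "tag", "t", "x", "y", "z")]
  attr(samples, "n_skipped") <- n_skipped
  samples
}

#' Write a motion sample table as a record stream
#'
#' Inverse of [read_motion_records()]: serializes a tidy sample table to the
#' line-delimited record format. Segment identity is carried implicitly by
#' tag runs, so `read_motion_records(write_motion_records(x))` restores the
#' same grouping for any table whose segments are tag runs.
#'
#' @param samples sample tibble as produced by [read_motion_records()] or
#'   [simulate_motion()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motion_records <- function(samples, path) {
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  out <- data.frame(
    participant = samples$participant_id,
    sensor = samples$sensor,
    study_day = samples$study_day,
    tag = samples$tag,
    segment = samples$segment_id,
    t = sprintf("%.17g", samples$t), x = sprintf("%.17g", samples$x),
    y = sprintf("%.17g", samples$y), z = sprintf("%.17g", samples$z)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged per-participant change table
#'
#' Returns the packaged table of per-participant study changes for the
#' 12 active-arm participants: clinical endpoint changes (Tampa Scale of
#' Kinesiophobia, overall-health VAS, EQ-5D-5L index; end of treatment
#' minus baseline, integer points) and movement velocity changes
#' (regression slope x VR study days, m/s) for the head, left-hand and
#' right-hand sensors.
#'
#' Participant 1054 is flagged `short_participation = TRUE`: that
#' participant had 11 VR study days against 29-30 for everyone else, and
#' correlation analyses are reported with and without them (see
#' [robustness_compare()]). The flag is data; exclusion is an analysis-time
#' decision, never automatic.
#'
#' @return A 12-row tibble with columns `subject`, `tampa_chg`, `vas_chg`,
#'   `eq5d_chg`, `head_chg`, `left_chg`, `right_chg`,
#'   `short_participation`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort_changes.csv",
                      package = "motionmark")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged change-table fixture is missing", call. = FALSE)
  }
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  expected <- c("subject", "tampa_chg", "vas_chg", "eq5d_chg",
                "head_chg", "left_chg", "right_chg", "short_participation")
  if (!identical(names(tab), expected) || nrow(tab) != 12L ||
      anyNA(tab[1:7]) || anyDuplicated(tab$subject) > 0L) {
    stop("packaged change-table fixture is corrupt", call. = FALSE)
  }
  tab$subject <- as.integer(tab$subject)
  tab
}

#' Read or write a clinical change table
#'
#' A clinical change table holds per-participant end-of-treatment minus
#' baseline changes: `tampa_chg` (Tampa Scale of Kinesiophobia points),
#' `vas_chg` (overall-health VAS points) and `eq5d_chg` (EQ-5D-5L summed
#' index points). Blank cells are preserved as missing values and handled
#' downstream by listwise deletion.
#'
#' @param source path to a CSV file with header
#'   `subject,tampa_chg,vas_chg,eq5d_chg` (extra columns are a schema
#'   error).
#' @return A tibble with one row per participant.
#' @export
read_clinical <- function(source) {
  tab <- as_tibble(read.csv(source, stringsAsFactors = FALSE))
  expected <- c("subject", "tampa_chg", "vas_chg", "eq5d_chg")
  unknown <- setdiff(names(tab), expected)
  if (length(unknown) > 0L) {
    stop("unknown clinical column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(tab))
  if (length(missing_cols) > 0L) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("tampa_chg", "vas_chg", "eq5d_chg")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  bad <- !is.na(tab$tampa_chg) & abs(tab$tampa_chg) > 68
  bad <- bad | (!is.na(tab$vas_chg) & abs(tab$vas_chg) > 100)
  if (any(bad)) {
    stop("clinical change out of scale range for subject(s): ",
         paste(tab$subject[bad], collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_clinical
#' @param clinical a clinical change tibble.
#' @param path output file path.
#' @export
write_clinical <- function(clinical, path) {
  write.csv(clinical[, c("subject", "tampa_chg", "vas_chg", "eq5d_chg")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write an electrodermal activity table
#'
#' Electrodermal activity (EDA, skin conductance in microsiemens) sampled
#' at a nominal 4 Hz, segmented like the motion data. Columns:
#' `participant`, `arm`, `segment_id`, `study_day`, `action_class`, `t`
#' (seconds), `value` (microsiemens). Timestamps must increase within a
#' segment and values must be finite.
#'
#' @param source path to the CSV file.
#' @return A tibble with columns `participant_id`, `arm`, `segment_id`,
#'   `study_day`, `action_class`, `t`, `value`.
#' @export
read_eda <- function(source) {
  tab <- as_tibble(read.csv(source, stringsAsFactors = FALSE))
  expected <- c("participant", "arm", "segment_id", "study_day",
                "action_class", "t", "value")
  unknown <- setdiff(names(tab), expected)
  if (length(unknown) > 0L) {
    stop("unknown EDA column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(tab))
  if (length(missing_cols) > 0L) {
    stop("EDA table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(tab$value)) || !all(is.finite(tab$t))) {
    stop("non-finite EDA timestamp or value", call. = FALSE)
  }
  dec <- tab %>%
    group_by(.data$segment_id) %>%
    summarise(ok = all(diff(.data$t) > 0) || n() < 2L, .groups = "drop")
  if (!all(dec$ok)) {
    stop("non-increasing timestamps within EDA segment(s): ",
         paste(dec$segment_id[!dec$ok], collapse = ", "), call. = FALSE)
  }
  tab %>%
    rename(participant_id = "participant") %>%
    mutate(study_day = as.integer(.data$study_day))
}

#' @rdname read_eda
#' @param eda an EDA tibble as returned by [read_eda()] or
#'   [simulate_eda()].
#' @param path output file path.
#' @export
write_eda <- function(eda, path) {
  out <- data.frame(
    participant = eda$participant_id, arm = eda$arm,
    segment_id = eda$segment_id, study_day = eda$study_day,
    action_class = eda$action_class,
    t = sprintf("%.17g", eda$t), value = sprintf("%.17g", eda$value)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a daily activity table
#'
#' Daily wrist-wearable aggregates: `steps` (non-negative integer),
#' `heart_rate_mean` (beats/min, may be missing) and `sleep_minutes`
#' (may be missing), per participant and 1-based study day.
#'
#' @param source path to a CSV file with header
#'   `participant,arm,study_day,steps,heart_rate_mean,sleep_minutes`.
#' @return A tibble with columns `participant_id`, `arm`, `study_day`,
#'   `steps`, `heart_rate_mean`, `sleep_minutes`.
#' @export
read_activity <- function(source) {
  tab <- as_tibble(read.csv(source, stringsAsFactors = FALSE))
  expected <- c("participant", "arm", "study_day", "steps",
                "heart_rate_mean", "sleep_minutes")
  unknown <- setdiff(names(tab), expected)
  if (length(unknown) > 0L) {
    stop("unknown activity column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(tab))
  if (length(missing_cols) > 0L) {
    stop("activity table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$steps)) || any(tab$steps < 0)) {
    stop("activity table has missing or negative step counts",
         call. = FALSE)
  }
  if (any(is.na(tab$study_day)) || any(tab$study_day < 1)) {
    stop("activity table has invalid study days", call. = FALSE)
  }
  tab %>%
    rename(participant_id = "participant") %>%
    mutate(study_day = as.integer(.data$study_day),
           steps = as.integer(.data$steps))
}

#' @rdname read_activity
#' @param activity an activity tibble.
#' @param path output file path.
#' @export
write_activity <- function(activity, path) {
  out <- data.frame(
    participant = activity$participant_id, arm = activity$arm,
    study_day = activity$study_day, steps = activity$steps,
    heart_rate_mean = activity$heart_rate_mean,
    sleep_minutes = activity$sleep_minutes
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
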