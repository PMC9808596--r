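#' Configure an end-to-end analysis run
#'
#' Collects everything [run_pipeline()] needs: exactly one data source —
#' a simulation spec, a set of input file paths, or the packaged change
#' table (`fixture = "table1"`) — plus the analysis knobs of the
#' individual stages.
#'
#' @param spec a [cohort_spec()] to simulate the cohort from.
#' @param inputs named list of file paths (`motion`, `eda`, `activity`,
#'   `clinical`) to read instead of simulating.
#' @param fixture `"table1"` to run the correlation stage on the packaged
#'   change table (other stages are skipped).
#' @param out_dir output directory for stage tables and the manifest.
#' @param stages which stages to run, a subset of
#'   `c("velocity", "eda", "activity", "correlate")`.
#' @param action_tags metadata tags counting as action.
#' @param gap_threshold,velocity_cap see [point_velocities()].
#' @param eda_band see [count_peaks()].
#' @param exclude participant ids flagged for the correlation robustness
#'   comparison.
#' @param methods correlation methods to run.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(spec = NULL, inputs = NULL, fixture = NULL,
                            out_dir,
                            stages = c("velocity", "eda", "activity",
                                       "correlate"),
                            action_tags = "task",
                            gap_threshold = 0.5, velocity_cap = NULL,
                            eda_band = "median_anchored",
                            exclude = NULL,
                            methods = c("pearson", "spearman")) {
  sources <- c(!is.null(spec), !is.null(inputs), !is.null(fixture))
  if (sum(sources) != 1L) {
    stop("provide exactly one of `spec`, `inputs`, `fixture`",
         call. = FALSE)
  }
  if (!is.null(fixture)) {
    fixture <- match.arg(fixture, "table1")
    stages <- "correlate"
  }
  stages <- match.arg(stages, c("velocity", "eda", "activity", "correlate"),
                      several.ok = TRUE)
  structure(
    list(spec = spec, inputs = inputs, fixture = fixture,
         out_dir = out_dir, stages = stages, action_tags = action_tags,
         gap_threshold = gap_threshold, velocity_cap = velocity_cap,
         eda_band = eda_band, exclude = exclude, methods = methods),
    class = "run_config"
  )
}

write_stage_table <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  path
}

write_matrix_table <- function(mat, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  df <- data.frame(variable = rownames(mat), round(mat, 2),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> segment velocities -> per-participant
#' change estimates -> electrodermal peak statistics -> weekly activity
#' trends -> correlation matrices, writing each stage's table to
#' `config$out_dir` as plain CSV plus a machine-readable `manifest.json`
#' (package version, configuration echo, per-stage log). Identical
#' configuration (including the spec seed) reproduces identical outputs.
#' A stage whose input is insufficient is skipped with the reason logged;
#' downstream stages needing its output are skipped too.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the stage outputs (`segments`,
#'   `changes`, `change_table`, `correlations`, `eda_stats`,
#'   `eda_summary`, `weekly_steps`, `step_trends`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  out <- list()

  motion <- eda <- activity <- clinical <- NULL
  if (!is.null(config$fixture)) {
    out$change_table <- load_table1_fixture()
    note("change table: packaged fixture (12 participants)")
  } else if (!is.null(config$spec)) {
    cohort <- simulate_cohort(config$spec)
    motion <- cohort$motion
    eda <- cohort$eda
    activity <- cohort$activity
    clinical <- cohort$clinical
    note("simulated cohort under seed %d", config$spec$seed)
  } else {
    if (!is.null(config$inputs$motion)) {
      motion <- read_motion_records(config$inputs$motion)
      note("motion: %d samples read, %d skipped", nrow(motion),
           attr(motion, "n_skipped"))
    }
    if (!is.null(config$inputs$eda)) eda <- read_eda(config$inputs$eda)
    if (!is.null(config$inputs$activity)) {
      activity <- read_activity(config$inputs$activity)
    }
    if (!is.null(config$inputs$clinical)) {
      clinical <- read_clinical(config$inputs$clinical)
    }
  }

  if ("velocity" %in% config$stages && !is.null(motion)) {
    segments <- segment_velocities(motion,
                                   gap_threshold = config$gap_threshold,
                                   velocity_cap = config$velocity_cap)
    segments <- classify_segment_context(segments,
                                         action_tags = config$action_tags)
    out$segments <- segments
    out$class_summary <- velocity_by_class_summary(segments)
    write_stage_table(segments, config$out_dir, "segment_velocities")
    write_stage_table(out$class_summary, config$out_dir,
                      "velocity_by_class")
    note("velocity: %d segments (%d pairs gap-skipped, %d capped, %d excluded)",
         nrow(segments), attr(segments, "n_skipped_gaps"),
         attr(segments, "n_dropped_cap"),
         attr(segments, "n_excluded_segments"))
    changes <- tryCatch(fit_daily_slope(segments), error = function(e) {
      note("slopes skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(changes)) {
      out$changes <- changes
      write_stage_table(changes, config$out_dir, "change_estimates")
      note("slopes: %d participant-sensor change estimates", nrow(changes))
    }
  } else if ("velocity" %in% config$stages) {
    note("velocity skipped: no motion data")
  }

  if ("eda" %in% config$stages && !is.null(eda)) {
    eda_kept <- filter_start_of_day(eda)
    stats <- eda_segment_stats(eda_kept, band = config$eda_band)
    out$eda_stats <- stats
    out$eda_summary <- arm_peak_summary(stats)
    write_stage_table(stats, config$out_dir, "eda_segment_stats")
    write_stage_table(out$eda_summary, config$out_dir,
                      "eda_participant_summary")
    note("eda: %d segments (%d start-of-day removed, %d excluded)",
         nrow(stats), attr(eda_kept, "n_removed_segments"),
         attr(stats, "n_excluded_segments"))
  } else if ("eda" %in% config$stages) {
    note("eda skipped: no EDA data")
  }

  if ("activity" %in% config$stages && !is.null(activity)) {
    out$weekly_steps <- weekly_step_changes(activity)
    out$step_trends <- participant_step_trends(activity)
    write_stage_table(out$weekly_steps, config$out_dir, "weekly_steps")
    write_stage_table(out$step_trends$slopes, config$out_dir,
                      "step_slopes")
    write_stage_table(out$step_trends$arm_summary, config$out_dir,
                      "step_arm_summary")
    note("activity: %d participant-weeks, %d step slopes",
         nrow(out$weekly_steps), nrow(out$step_trends$slopes))
  } else if ("activity" %in% config$stages) {
    note("activity skipped: no activity data")
  }

  if ("correlate" %in% config$stages) {
    if (is.null(out$change_table)) {
      if (!is.null(out$changes) && !is.null(clinical)) {
        wide <- out$changes %>%
          select("participant_id", "sensor", "change") %>%
          tidyr::pivot_wider(names_from = "sensor",
                             values_from = "change") %>%
          rename(head_chg = "head", left_chg = "left",
                 right_chg = "right")
        names(clinical)[names(clinical) == "participant_id"] <- "subject"
        names(wide)[names(wide) == "participant_id"] <- "subject"
        out$change_table <- dplyr::inner_join(clinical, wide,
                                              by = "subject")
      } else {
        note("correlate skipped: no change table available")
      }
    }
    if (!is.null(out$change_table)) {
      write_stage_table(out$change_table, config$out_dir, "change_table")
      out$correlations <- list()
      for (m in config$methods) {
        if (length(config$exclude) > 0L) {
          cmp <- robustness_compare(out$change_table, config$exclude,
                                    method = m)
          out$correlations[[m]] <- cmp
          write_matrix_table(cmp$full$matrix, config$out_dir,
                             paste0("correlations_", m, "_full"))
          write_matrix_table(cmp$excluded$matrix, config$out_dir,
                             paste0("correlations_", m, "_excluded"))
          note("correlate (%s): n=%d full, n=%d excluding %s", m,
               cmp$full$n_used, cmp$excluded$n_used,
               paste(config$exclude, collapse = ","))
        } else {
          rep <- correlation_matrix(out$change_table, method = m)
          out$correlations[[m]] <- rep
          write_matrix_table(rep$matrix, config$out_dir,
                             paste0("correlations_", m, "_full"))
          note("correlate (%s): n=%d", m, rep$n_used)
        }
      }
    }
  }

  manifest <- list(
    package = "motionmark",
    version = as.character(utils::packageVersion("motionmark")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (!is.null(config$spec)) config$spec$seed else NULL,
    stages = config$stages,
    fixture = config$fixture,
    action_tags = config$action_tags,
    gap_threshold = config$gap_threshold,
    velocity_cap = config$velocity_cap,
    eda_band = config$eda_band,
    exclude = config$exclude,
    methods = config$methods,
    log = log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  out$manifest <- manifest
  invisible(out)
}
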