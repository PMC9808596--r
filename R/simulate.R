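#' Specify a synthetic cohort
#'
#' Builds the parameter list that drives all four synthetic data
#' generators ([simulate_motion()], [simulate_clinical()],
#' [simulate_eda()], [simulate_activity()]). The defaults describe a
#' desk-scale cohort with the structure the analysis assumes: 12
#' active-arm (DTxP) participants doing about 30 daily VR sessions of 10
#' action task segments and 3 task-free segments, with a small positive
#' mean improvement in movement velocity over the study, a clinical link
#' of configurable strength between latent movement change and endpoint
#' changes, sparse phasic electrodermal pulses on a slow tonic drift, and
#' arm-specific weekly step trends.
#'
#' @param n_participants number of active-arm participants.
#' @param n_study_days number of VR study days per participant.
#' @param action_segments_per_day action task segments per day.
#' @param noaction_segments_per_day task-free segments per day, placed as
#'   start-of-day, between-action and end-of-day context.
#' @param segment_duration_s motion/EDA segment duration, seconds.
#' @param sample_rate_motion motion sampling rate, Hz.
#' @param sample_rate_eda electrodermal sampling rate, Hz.
#' @param baseline_velocity named vector, day-zero action-segment mean
#'   velocity (m/s) for sensors `head`, `left`, `right`.
#' @param improvement_slope_mean,improvement_slope_sd mean and sd of the
#'   per-participant latent daily velocity improvement (m/s per study
#'   day), shared across sensors.
#' @param segment_velocity_sd sd of per-segment mean velocity around the
#'   participant-day latent mean (m/s).
#' @param action_vs_noaction_velocity_ratio action-segment mean velocity
#'   divided by task-free-segment mean velocity; must exceed 1.
#' @param clinical_link_strength target correlation (in `[-1, 1]`) between
#'   latent movement change and each clinical change, before sign
#'   conventions and integer rounding.
#' @param clinical_center,clinical_scale named vectors (`tampa`, `vas`,
#'   `eq5d`): location and scale, in scale points, of simulated clinical
#'   changes.
#' @param eda_pulse_rate named vector of phasic pulse rates per arm
#'   (pulses/minute, Poisson arrivals).
#' @param eda_pulse_amplitude pulse onset amplitude, microsiemens.
#' @param eda_pulse_tau exponential pulse decay constant, seconds.
#' @param eda_tonic_amplitude range (2-vector, microsiemens) of the slow
#'   sinusoidal tonic wave's amplitude, drawn per segment.
#' @param eda_tonic_period range (2-vector, seconds) of the tonic wave's
#'   period, drawn per segment.
#' @param eda_tonic_drift_sd per-sample sd of an additional tonic
#'   random-walk drift, microsiemens.
#' @param eda_noise_sd white measurement noise sd, microsiemens (default
#'   on the order of the recording device's resolution).
#' @param eda_study_days study days of EDA recording (defaults to
#'   `n_study_days`).
#' @param eda_segment_duration_s EDA segment duration in seconds
#'   (defaults to `segment_duration_s`); peak rates need minutes-scale
#'   segments to be stable.
#' @param n_sham,n_standardcare arm sizes for the sham and standard-care
#'   arms (EDA uses DTxP + Sham; activity uses all three).
#' @param steps_baseline mean daily steps at week 1.
#' @param steps_weekly_trend named vector of per-arm weekly step trends
#'   (steps/day added per week).
#' @param steps_noise_sd daily step noise sd.
#' @param n_activity_days days of activity recording per participant.
#' @param seed integer seed; every generator is fully deterministic given
#'   the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 12,
                        n_study_days = 30,
                        action_segments_per_day = 10,
                        noaction_segments_per_day = 3,
                        segment_duration_s = 60,
                        sample_rate_motion = 30,
                        sample_rate_eda = 4,
                        baseline_velocity = c(head = 0.5, left = 0.7,
                                              right = 0.8),
                        improvement_slope_mean = 0.003,
                        improvement_slope_sd = 0.002,
                        segment_velocity_sd = 0.05,
                        action_vs_noaction_velocity_ratio = 2,
                        clinical_link_strength = 0.6,
                        clinical_center = c(tampa = -6, vas = 20, eq5d = -2),
                        clinical_scale = c(tampa = 5, vas = 25, eq5d = 3),
                        eda_pulse_rate = c(DTxP = 3, Sham = 1.5),
                        eda_pulse_amplitude = 0.3,
                        eda_pulse_tau = 2,
                        eda_tonic_amplitude = c(0.4, 0.8),
                        eda_tonic_period = c(15, 30),
                        eda_tonic_drift_sd = 5e-4,
                        eda_noise_sd = 5e-4,
                        eda_study_days = NULL,
                        eda_segment_duration_s = NULL,
                        n_sham = 17,
                        n_standardcare = 10,
                        steps_baseline = 6000,
                        steps_weekly_trend = c(DTxP = 200, Sham = 0,
                                               StandardCare = 0),
                        steps_noise_sd = 800,
                        n_activity_days = 56,
                        seed = 20201) {
  spec <- list(
    n_participants = as.integer(n_participants),
    n_study_days = as.integer(n_study_days),
    action_segments_per_day = as.integer(action_segments_per_day),
    noaction_segments_per_day = as.integer(noaction_segments_per_day),
    segment_duration_s = segment_duration_s,
    sample_rate_motion = sample_rate_motion,
    sample_rate_eda = sample_rate_eda,
    baseline_velocity = baseline_velocity,
    improvement_slope_mean = improvement_slope_mean,
    improvement_slope_sd = improvement_slope_sd,
    segment_velocity_sd = segment_velocity_sd,
    action_vs_noaction_velocity_ratio = action_vs_noaction_velocity_ratio,
    clinical_link_strength = clinical_link_strength,
    clinical_center = clinical_center,
    clinical_scale = clinical_scale,
    eda_pulse_rate = eda_pulse_rate,
    eda_pulse_amplitude = eda_pulse_amplitude,
    eda_pulse_tau = eda_pulse_tau,
    eda_tonic_amplitude = eda_tonic_amplitude,
    eda_tonic_period = eda_tonic_period,
    eda_tonic_drift_sd = eda_tonic_drift_sd,
    eda_noise_sd = eda_noise_sd,
    eda_study_days = as.integer(eda_study_days %||% n_study_days),
    eda_segment_duration_s = eda_segment_duration_s %||% segment_duration_s,
    n_sham = as.integer(n_sham),
    n_standardcare = as.integer(n_standardcare),
    steps_baseline = steps_baseline,
    steps_weekly_trend = steps_weekly_trend,
    steps_noise_sd = steps_noise_sd,
    n_activity_days = as.integer(n_activity_days),
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_cohort_spec <- function(spec) {
  stopifnot(
    spec$n_participants >= 2L,
    spec$n_study_days >= 1L,
    spec$action_segments_per_day >= 1L,
    spec$noaction_segments_per_day >= 0L,
    spec$segment_duration_s > 0,
    spec$sample_rate_motion > 0, spec$sample_rate_eda > 0,
    all(spec$baseline_velocity > 0),
    identical(sort(names(spec$baseline_velocity)), sort(SENSORS)),
    spec$segment_velocity_sd >= 0,
    spec$action_vs_noaction_velocity_ratio > 1,
    abs(spec$clinical_link_strength) <= 1,
    all(spec$eda_pulse_rate >= 0),
    spec$eda_pulse_amplitude >= 0, spec$eda_pulse_tau > 0,
    length(spec$eda_tonic_amplitude) == 2L,
    all(spec$eda_tonic_amplitude >= 0),
    length(spec$eda_tonic_period) == 2L, all(spec$eda_tonic_period > 0),
    spec$eda_tonic_drift_sd >= 0, spec$eda_noise_sd >= 0,
    spec$eda_segment_duration_s > 0,
    spec$steps_noise_sd >= 0
  )
  if (spec$action_segments_per_day + spec$noaction_segments_per_day < 1L) {
    stop("spec defines zero segments per day", call. = FALSE)
  }
  invisible(spec)
}

# deterministic sub-seed per generator stage so the four streams are
# mutually independent but individually reproducible
stage_seed <- function(spec, offset) {
  as.integer((as.numeric(spec$seed) * 7L + offset) %% 2147483647)
}

#' Draw per-participant latent improvement effects
#'
#' Draws each active-arm participant's latent daily velocity improvement
#' `beta` (m/s per study day, shared across sensors) and the implied
#' latent movement change over the study, `beta * n_study_days`. These
#' effects are the ground truth that parameter-recovery tests compare
#' fitted slopes and recovered correlations against.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `participant_id`, `beta`,
#'   `latent_change`.
#' @export
draw_participant_effects <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(stage_seed(spec, 0L))
  tibble(
    participant_id = sprintf("P%03d", seq_len(spec$n_participants)),
    beta = rnorm(spec$n_participants, spec$improvement_slope_mean,
                 spec$improvement_slope_sd),
    latent_change = NA_real_
  ) %>%
    mutate(latent_change = .data$beta * spec$n_study_days)
}

# Day layout: ordered action classes for one study day. Task-free
# segments are placed first (start of day), in the middle of the action
# run (between) and last (end of day).
day_segment_layout <- function(n_action, n_noaction) {
  if (n_noaction == 0L) {
    return(rep("action", n_action))
  }
  n_start <- 1L
  n_end <- if (n_noaction >= 2L) 1L else 0L
  n_between <- n_noaction - n_start - n_end
  actions <- rep("action", n_action)
  if (n_between > 0L) {
    # spread the between segments evenly through the action run
    at <- floor(seq_len(n_between) * n_action / (n_between + 1L))
    body <- character(0)
    prev <- 0L
    for (i in seq_len(n_between)) {
      body <- c(body, actions[seq_len(at[i] - prev) + prev],
                "no_action_between")
      prev <- at[i]
    }
    body <- c(body, if (prev < n_action) actions[(prev + 1L):n_action])
  } else {
    body <- actions
  }
  c(rep("no_action_start_of_day", n_start), body,
    rep("no_action_end_of_day", n_end))
}

#' Simulate per-segment target mean velocities
#'
#' The segment-level layer of the motion generator. For participant `p`,
#' sensor `s` and study day `d`, the latent action-segment mean velocity
#' is `v0(s) + beta(p) * d`; individual action segments draw their target
#' mean around it with sd `segment_velocity_sd`, and task-free segments
#' use the latent mean divided by the action/no-action ratio. The
#' trajectory layer ([simulate_motion()]) then realizes each segment as a
#' random walk whose per-step speed equals the segment target exactly, so
#' the per-segment average velocity measured downstream equals the target
#' up to floating-point error; slope estimation on the two layers is the
#' same computation.
#'
#' @param spec a [cohort_spec()].
#' @param effects participant effects from [draw_participant_effects()];
#'   drawn from the spec when omitted.
#' @return A tibble with one row per segment: `participant_id`, `sensor`,
#'   `study_day`, `segment_id`, `tag`, `action_class`,
#'   `target_velocity` (m/s), `duration_s`.
#' @export
simulate_segment_means <- function(spec, effects = NULL) {
  validate_cohort_spec(spec)
  effects <- effects %||% draw_participant_effects(spec)
  layout <- day_segment_layout(spec$action_segments_per_day,
                               spec$noaction_segments_per_day)
  n_slots <- length(layout)
  grid <- tidyr::expand_grid(
    participant_id = effects$participant_id,
    sensor = SENSORS,
    study_day = seq_len(spec$n_study_days),
    slot = seq_len(n_slots)
  ) %>%
    mutate(action_class = layout[.data$slot],
           tag = ifelse(.data$action_class == "action", "task", "idle"),
           segment_id = sprintf("%s_%s_d%02d_s%03d", .data$participant_id,
                                .data$sensor, .data$study_day, .data$slot)) %>%
    left_join(effects[, c("participant_id", "beta")], by = "participant_id")
  set.seed(stage_seed(spec, 1L))
  latent <- spec$baseline_velocity[grid$sensor] +
    grid$beta * grid$study_day
  is_action <- grid$action_class == "action"
  target <- ifelse(is_action, latent,
                   latent / spec$action_vs_noaction_velocity_ratio) +
    rnorm(nrow(grid), 0, spec$segment_velocity_sd)
  grid %>%
    mutate(target_velocity = pmax(target, 1e-6),
           duration_s = spec$segment_duration_s) %>%
    select("participant_id", "sensor", "study_day", "segment_id", "tag",
           "action_class", "target_velocity", "duration_s")
}

#' Simulate raw motion sample streams
#'
#' Generates tri-axial position samples for every segment of every
#' active-arm participant and sensor. Each segment is a random walk: unit
#' random directions with per-step displacement magnitude
#' `target_velocity / sample_rate`, so each consecutive-pair speed (and
#' hence the segment's average velocity) equals the segment target
#' exactly. Segments within a day are laid out sequentially in session
#' time with a 5 s silent gap between them.
#'
#' @param spec a [cohort_spec()].
#' @param effects optional participant effects (drawn from the spec when
#'   omitted).
#' @return A sample tibble (columns as [read_motion_records()]) with
#'   attributes `effects` (ground-truth participant effects) and
#'   `segment_means` (the segment-level targets).
#' @export
simulate_motion <- function(spec, effects = NULL) {
  validate_cohort_spec(spec)
  effects <- effects %||% draw_participant_effects(spec)
  means <- simulate_segment_means(spec, effects)
  n_per_seg <- max(2L, as.integer(round(spec$segment_duration_s *
                                          spec$sample_rate_motion)))
  dt <- 1 / spec$sample_rate_motion
  n_seg <- nrow(means)
  total <- n_seg * n_per_seg

  set.seed(stage_seed(spec, 2L))
  # unit step directions for every sample; the first sample of a segment
  # is the walk origin and takes no step
  dir <- matrix(rnorm(total * 3L), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  step_len <- rep(means$target_velocity * dt, each = n_per_seg)
  first_of_seg <- rep(c(TRUE, rep(FALSE, n_per_seg - 1L)), n_seg)
  step <- dir * step_len
  step[first_of_seg, ] <- 0
  origin <- matrix(runif(n_seg * 3L, -1, 1), ncol = 3L)

  seg_index <- rep(seq_len(n_seg), each = n_per_seg)
  pos <- apply(step, 2L, cumsum)
  # reset each segment's walk to its own origin
  seg_base <- pos[first_of_seg, , drop = FALSE]
  pos <- pos - seg_base[seg_index, ] + origin[seg_index, ]

  # session clock: segments of a participant-sensor-day run back to back
  # with a 5 s gap
  slot <- stats::ave(seq_len(n_seg),
                     paste(means$participant_id, means$sensor,
                           means$study_day, sep = "\r"),
                     FUN = seq_along)
  seg_start <- (slot - 1L) * (spec$segment_duration_s + 5)
  t <- rep(seg_start, each = n_per_seg) +
    rep(seq_len(n_per_seg) - 1L, n_seg) * dt

  samples <- tibble(
    participant_id = rep(means$participant_id, each = n_per_seg),
    sensor = rep(means$sensor, each = n_per_seg),
    study_day = rep(means$study_day, each = n_per_seg),
    segment_id = rep(means$segment_id, each = n_per_seg),
    tag = rep(means$tag, each = n_per_seg),
    t = t, x = pos[, 1L], y = pos[, 2L], z = pos[, 3L]
  )
  attr(samples, "effects") <- effects
  attr(samples, "segment_means") <- means
  samples
}

#' Simulate clinical endpoint changes linked to movement change
#'
#' Maps each participant's latent movement change `m(p)` (true slope times
#' study days) to integer clinical endpoint changes through a linear
#' Gaussian link: with `z(p)` the cohort-standardized `m(p)` and `rho` the
#' configured link strength, each endpoint change is
#' `center + scale * (sign * rho * z(p) + sqrt(1 - rho^2) * eps(p))`,
#' `eps ~ N(0, 1)`. Signs follow the clinical direction conventions:
#' negative for the Tampa kinesiophobia scale and the EQ-5D-5L index
#' (more movement improvement, lower score) and positive for the
#' overall-health VAS.
#'
#' @param spec a [cohort_spec()].
#' @param motion a motion sample tibble from [simulate_motion()], whose
#'   `effects` attribute carries the latent changes; alternatively pass
#'   `effects` directly.
#' @param effects participant effects tibble (overrides `motion`).
#' @param round_to_integer round changes to whole scale points (the
#'   resolution of the clinical instruments)? Default `TRUE`.
#' @return A tibble with columns `participant_id`, `tampa_chg`,
#'   `vas_chg`, `eq5d_chg`.
#' @export
simulate_clinical <- function(spec, motion = NULL, effects = NULL,
                              round_to_integer = TRUE) {
  validate_cohort_spec(spec)
  effects <- effects %||% attr(motion, "effects")
  if (is.null(effects)) {
    stop("supply `motion` from simulate_motion() or `effects`",
         call. = FALSE)
  }
  if (nrow(effects) != spec$n_participants) {
    stop("participant set in effects does not match the spec",
         call. = FALSE)
  }
  m <- effects$latent_change
  z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, length(m))
  rho <- spec$clinical_link_strength
  signs <- c(tampa = -1, vas = 1, eq5d = -1)
  set.seed(stage_seed(spec, 3L))
  out <- tibble(participant_id = effects$participant_id)
  for (ep in names(signs)) {
    eps <- rnorm(length(m))
    val <- spec$clinical_center[[ep]] + spec$clinical_scale[[ep]] *
      (signs[[ep]] * rho * z + sqrt(1 - rho^2) * eps)
    if (round_to_integer) val <- round(val)
    out[[paste0(ep, "_chg")]] <- val
  }
  out
}

# One segment of EDA: exponential-decay pulses on a slow tonic.
# The tonic is a sinusoid (bounded derivative) plus a small random walk;
# keeping the white-noise and drift scales well below the wave's
# per-sample increment keeps the differenced background bounded, so the
# median + 2*MAD band separates genuine phasic pulses from background
# rather than clipping a fixed quantile of diffuse noise.
simulate_eda_segment <- function(n, rate_hz, pulse_per_min, amplitude, tau,
                                 tonic_amp, tonic_period, tonic_sd,
                                 noise_sd, level0) {
  t <- (seq_len(n) - 1L) / rate_hz
  dur_min <- (n - 1L) / rate_hz / 60
  wave_a <- runif(1L, tonic_amp[1L], tonic_amp[2L])
  wave_p <- runif(1L, tonic_period[1L], tonic_period[2L])
  phase <- runif(1L, 0, 2 * pi)
  tonic <- level0 + wave_a * sin(2 * pi * t / wave_p + phase) +
    cumsum(rnorm(n, 0, tonic_sd))
  phasic <- numeric(n)
  n_pulse <- rpois(1L, pulse_per_min * dur_min)
  if (n_pulse > 0L) {
    onsets <- runif(n_pulse, 0, max(t))
    for (t0 in onsets) {
      after <- t >= t0
      phasic[after] <- phasic[after] + amplitude * exp(-(t[after] - t0) / tau)
    }
  }
  list(t = t, value = tonic + phasic + rnorm(n, 0, noise_sd),
       n_pulse = n_pulse)
}

#' Simulate electrodermal activity streams
#'
#' Generates segmented skin-conductance series for the active (DTxP) and
#' sham arms: a slow tonic component (a low-frequency sinusoidal wave
#' with per-segment amplitude and period, plus a small random-walk
#' drift), sparse phasic pulses (Poisson arrivals at the arm's configured
#' rate, instantaneous rise and exponential decay) and white measurement
#' noise at the scale of the device resolution. Active-arm segments
#' follow the same day layout and context labels as the motion data; sham
#' segments are all task-free (`no_action_between`), matching the
#' assumption that sham sessions contain no task activity.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `participant_id`, `arm`, `segment_id`,
#'   `study_day`, `action_class`, `t`, `value`, with attribute
#'   `true_pulses` (per-segment injected pulse counts).
#' @export
simulate_eda <- function(spec) {
  validate_cohort_spec(spec)
  layout <- day_segment_layout(spec$action_segments_per_day,
                               spec$noaction_segments_per_day)
  plan <- bind_rows(
    tidyr::expand_grid(
      participant_id = sprintf("P%03d", seq_len(spec$n_participants)),
      arm = "DTxP",
      study_day = seq_len(spec$eda_study_days),
      slot = seq_along(layout)
    ) %>% mutate(action_class = layout[.data$slot]),
    tidyr::expand_grid(
      participant_id = sprintf("S%03d", seq_len(spec$n_sham)),
      arm = "Sham",
      study_day = seq_len(spec$eda_study_days),
      slot = seq_along(layout)
    ) %>% mutate(action_class = "no_action_between")
  ) %>%
    mutate(segment_id = sprintf("%s_d%02d_e%03d", .data$participant_id,
                                .data$study_day, .data$slot))
  n <- max(2L, as.integer(round(spec$eda_segment_duration_s *
                                  spec$sample_rate_eda)))
  set.seed(stage_seed(spec, 4L))
  level0 <- runif(nrow(plan), 0.5, 3)
  segs <- vector("list", nrow(plan))
  true_pulses <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- simulate_eda_segment(
      n, spec$sample_rate_eda,
      spec$eda_pulse_rate[[plan$arm[i]]],
      spec$eda_pulse_amplitude, spec$eda_pulse_tau,
      spec$eda_tonic_amplitude, spec$eda_tonic_period,
      spec$eda_tonic_drift_sd, spec$eda_noise_sd, level0[i]
    )
    true_pulses[i] <- s$n_pulse
    segs[[i]] <- tibble(
      participant_id = plan$participant_id[i], arm = plan$arm[i],
      segment_id = plan$segment_id[i], study_day = plan$study_day[i],
      action_class = plan$action_class[i], t = s$t, value = s$value
    )
  }
  out <- bind_rows(segs)
  attr(out, "true_pulses") <-
    tibble(segment_id = plan$segment_id, n_pulse = true_pulses)
  out
}

#' Simulate daily activity aggregates
#'
#' Daily step counts for all three arms: baseline plus the arm's weekly
#' trend (accrued linearly per day) plus Gaussian noise, truncated at zero
#' and rounded to whole steps. Mean heart rate and sleep duration are
#' generated as uninformative descriptive columns.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `participant_id`, `arm`, `study_day`,
#'   `steps`, `heart_rate_mean`, `sleep_minutes`.
#' @export
simulate_activity <- function(spec) {
  validate_cohort_spec(spec)
  ids <- c(sprintf("P%03d", seq_len(spec$n_participants)),
           sprintf("S%03d", seq_len(spec$n_sham)),
           sprintf("C%03d", seq_len(spec$n_standardcare)))
  arms <- rep(ARMS, c(spec$n_participants, spec$n_sham,
                      spec$n_standardcare))
  grid <- tidyr::expand_grid(
    i = seq_along(ids),
    study_day = seq_len(spec$n_activity_days)
  )
  set.seed(stage_seed(spec, 5L))
  trend <- spec$steps_weekly_trend[arms[grid$i]]
  raw <- spec$steps_baseline + trend * (grid$study_day - 1) / 7 +
    rnorm(nrow(grid), 0, spec$steps_noise_sd)
  tibble(
    participant_id = ids[grid$i],
    arm = arms[grid$i],
    study_day = as.integer(grid$study_day),
    steps = as.integer(round(pmax(raw, 0))),
    heart_rate_mean = round(rnorm(nrow(grid), 72, 5), 1),
    sleep_minutes = round(pmax(rnorm(nrow(grid), 420, 45), 0))
  )
}

#' Simulate a complete cohort
#'
#' Runs all four generators from one spec and returns their outputs with
#' the shared ground-truth effects.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `effects`, `motion`, `clinical`, `eda`,
#'   `activity`.
#' @export
simulate_cohort <- function(spec) {
  effects <- draw_participant_effects(spec)
  motion <- simulate_motion(spec, effects)
  list(
    effects = effects,
    motion = motion,
    clinical = simulate_clinical(spec, effects = effects),
    eda = simulate_eda(spec),
    activity = simulate_activity(spec)
  )
}
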