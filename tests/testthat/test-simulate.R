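test_that("spec validation rejects impossible cohorts", {
  expect_error(cohort_spec(n_participants = 1))
  expect_error(cohort_spec(clinical_link_strength = 1.5))
  expect_error(cohort_spec(action_vs_noaction_velocity_ratio = 1))
  expect_error(cohort_spec(segment_duration_s = 0))
})

test_that("every generator is deterministic under a fixed seed", {
  spec <- tiny_spec()
  expect_identical(simulate_motion(spec), simulate_motion(spec))
  expect_identical(simulate_eda(spec), simulate_eda(spec))
  expect_identical(simulate_activity(spec), simulate_activity(spec))
  eff <- draw_participant_effects(spec)
  expect_identical(simulate_clinical(spec, effects = eff),
                   simulate_clinical(spec, effects = eff))
  # a different seed changes the draw
  spec2 <- tiny_spec(seed = 8)
  expect_false(identical(simulate_motion(spec)$x,
                         simulate_motion(spec2)$x))
})

test_that("generated motion obeys the data-model invariants", {
  sim <- simulate_motion(tiny_spec())
  expect_true(all(is.finite(sim$t)), all(is.finite(sim$x)))
  expect_true(all(sim$sensor %in% c("head", "left", "right")))
  expect_true(all(sim$study_day >= 1))
  inc <- tapply(sim$t, sim$segment_id, function(t) all(diff(t) > 0))
  expect_true(all(inc))
})

test_that("trajectories realize their segment target velocities exactly", {
  sim <- simulate_motion(tiny_spec())
  means <- attr(sim, "segment_means")
  segs <- segment_velocities(sim)
  j <- merge(segs, means[, c("segment_id", "target_velocity")],
             by = "segment_id")
  expect_equal(j$mean_velocity, j$target_velocity, tolerance = 1e-12)
})

test_that("a noise-free cohort returns the injected slope exactly", {
  spec <- tiny_spec(segment_velocity_sd = 0)
  sim <- simulate_motion(spec)
  eff <- attr(sim, "effects")
  fit <- fit_daily_slope(classify_segment_context(segment_velocities(sim)))
  j <- merge(fit, eff, by = "participant_id")
  expect_equal(j$slope, j$beta, tolerance = 1e-9)
  expect_equal(nrow(j), spec$n_participants * 3L)
})

test_that("the mean fitted slope is unbiased for the injected improvement", {
  # Monte-Carlo check on the segment-mean layer (shown above to be what
  # the trajectory layer reproduces exactly)
  n_rep <- 30
  errs <- numeric(0)
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(n_participants = 6, n_study_days = 15,
                        action_segments_per_day = 5,
                        noaction_segments_per_day = 0,
                        improvement_slope_mean = 0.003,
                        improvement_slope_sd = 0,
                        eda_study_days = 1, n_sham = 2,
                        n_standardcare = 2, n_activity_days = 7,
                        seed = 1000 + r)
    means <- simulate_segment_means(spec)
    act <- means[means$action_class == "action" & means$sensor == "head", ]
    for (p in unique(act$participant_id)) {
      rows <- act[act$participant_id == p, ]
      errs <- c(errs, oracle_slope(rows$study_day, rows$target_velocity) -
                  0.003)
    }
  }
  mc_se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * mc_se + 1e-12)
})

test_that("the clinical link is exact when degenerate and near zero when off", {
  spec <- tiny_spec(n_participants = 10, clinical_link_strength = 1)
  eff <- draw_participant_effects(spec)
  cl <- simulate_clinical(spec, effects = eff, round_to_integer = FALSE)
  expect_equal(abs(cor(eff$latent_change, cl$vas_chg)), 1,
               tolerance = 1e-9)
  expect_equal(cor(eff$latent_change, cl$tampa_chg), -1, tolerance = 1e-9)

  # with no link, sample correlations at n = 50 scatter around zero
  # with sd near 1/sqrt(n - 1) = 0.143, so |r| < 0.2 about 84% of the
  # time; assert the mean near zero and the coverage above a 3-sigma
  # lower bound of that derived rate
  rs <- vapply(1:40, function(r) {
    spec0 <- tiny_spec(n_participants = 50, clinical_link_strength = 0,
                       seed = 2000 + r)
    eff0 <- draw_participant_effects(spec0)
    cl0 <- simulate_clinical(spec0, effects = eff0)
    cor(eff0$latent_change, cl0$vas_chg)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
  expect_gte(mean(abs(rs) < 0.2), 0.66)
})

test_that("a 0.6 link is recovered on average at the trial's own n = 12", {
  rs <- vapply(1:200, function(r) {
    spec <- tiny_spec(n_participants = 12, clinical_link_strength = 0.6,
                      seed = 3000 + r)
    eff <- draw_participant_effects(spec)
    cl <- simulate_clinical(spec, effects = eff)
    cor(eff$latent_change, cl$vas_chg)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("clinical changes mirror the published direction pattern", {
  spec <- tiny_spec(n_participants = 40, clinical_link_strength = 0.8,
                    seed = 5)
  eff <- draw_participant_effects(spec)
  cl <- simulate_clinical(spec, effects = eff)
  expect_lt(cor(eff$latent_change, cl$tampa_chg), 0)
  expect_gt(cor(eff$latent_change, cl$vas_chg), 0)
  expect_lt(cor(eff$latent_change, cl$eq5d_chg), 0)
})

test_that("clinical simulation demands a matching participant set", {
  spec <- tiny_spec()
  eff <- draw_participant_effects(tiny_spec(n_participants = 5))
  expect_error(simulate_clinical(spec, effects = eff), "participant set")
  expect_error(simulate_clinical(spec), "supply")
})

test_that("a noise- and pulse-free signal yields zero peaks", {
  spec <- tiny_spec(eda_pulse_rate = c(DTxP = 0, Sham = 0),
                    eda_noise_sd = 0, eda_tonic_drift_sd = 0,
                    eda_tonic_amplitude = c(0, 0),
                    segment_duration_s = 60)
  eda <- simulate_eda(spec)
  stats <- eda_segment_stats(eda)
  expect_true(all(stats$peak_count == 0L))
  expect_true(all(stats$degenerate_band))
})

test_that("activity is constant without trend and noise, and truncated at 0", {
  spec <- tiny_spec(steps_noise_sd = 0,
                    steps_weekly_trend = c(DTxP = 0, Sham = 0,
                                           StandardCare = 0))
  act <- simulate_activity(spec)
  expect_true(all(act$steps == spec$steps_baseline))
  low <- tiny_spec(steps_baseline = 10, steps_noise_sd = 2000)
  act2 <- simulate_activity(low)
  expect_true(all(act2$steps >= 0L))
  expect_true(any(act2$steps == 0L))
})

test_that("simulate_cohort wires all four streams to one ground truth", {
  spec <- tiny_spec()
  cohort <- simulate_cohort(spec)
  expect_identical(cohort$effects, attr(cohort$motion, "effects"))
  expect_equal(sort(unique(cohort$motion$participant_id)),
               sort(cohort$effects$participant_id))
  expect_equal(nrow(cohort$clinical), spec$n_participants)
  expect_true(all(c("DTxP", "Sham") %in% cohort$eda$arm))
  expect_true(all(c("DTxP", "Sham", "StandardCare") %in%
                    cohort$activity$arm))
})
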