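seg_from <- function(t, x, y, z) {
  tibble::tibble(t = t, x = x, y = y, z = z, segment_id = "s",
                 sensor = "head", study_day = 1L, tag = "task")
}

test_that("point velocities match hand computations", {
  # 3-4-5 displacement over 0.1 s -> 5 m/s
  seg <- seg_from(c(0, 0.1), c(0, 0.3), c(0, 0.4), c(0, 0))
  pts <- point_velocities(seg)
  expect_equal(pts$v, 5.0)
  expect_equal(pts$t, 0.1)
  # a stationary sensor has zero velocity everywhere
  seg <- seg_from(seq(0, 1, by = 0.1), rep(1, 11), rep(2, 11), rep(3, 11))
  expect_equal(point_velocities(seg)$v, rep(0, 10))
})

test_that("point velocities equal the brute-force oracle on random segments", {
  set.seed(101)
  for (i in 1:50) {
    seg <- random_segment(n = sample(10:100, 1))
    got <- point_velocities(seg)
    ref <- oracle_point_velocities(seg)
    expect_equal(got$v, ref$v, tolerance = 0)
    expect_equal(got$t, ref$t, tolerance = 0)
  }
})

test_that("gap threshold skips pairs and the cap drops fast points, with counts", {
  t <- c(0, 0.03, 1.0, 1.03, 1.06)
  seg <- seg_from(t, c(0, 0.001, 0.002, 0.5, 0.503), rep(0, 5), rep(0, 5))
  pts <- point_velocities(seg, gap_threshold = 0.5)
  expect_equal(nrow(pts), 3L)          # the 0.97 s gap pair is skipped
  expect_equal(attr(pts, "n_skipped_gaps"), 1L)
  capped <- point_velocities(seg, gap_threshold = 0.5, velocity_cap = 10)
  expect_equal(nrow(capped), 2L)       # the 0.5 m jump in 30 ms exceeds cap
  expect_equal(attr(capped, "n_dropped_cap"), 1L)
  # non-positive dt is skipped too
  seg2 <- seg_from(c(0, 0.03, 0.03), c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  expect_equal(attr(point_velocities(seg2), "n_skipped_gaps"), 1L)
})

test_that("a segment with fewer than two usable samples yields no points", {
  seg <- seg_from(0, 0, 0, 0)
  expect_equal(nrow(point_velocities(seg)), 0L)
})

test_that("segment mean velocity is the arithmetic mean with timestamp duration", {
  seg <- seg_from(c(0, 1, 2), c(0, 1, 4), rep(0, 3), rep(0, 3))
  pts <- point_velocities(seg, gap_threshold = 2)
  sv <- segment_mean_velocity(pts, seg)
  expect_equal(sv$mean_velocity, 2.0)  # (1 + 3) / 2
  expect_equal(sv$duration, 2)
  expect_equal(sv$n_points, 2L)
  one <- segment_mean_velocity(pts[1, ], seg)
  expect_equal(one$mean_velocity, pts$v[1])
  expect_null(segment_mean_velocity(pts[0, ], seg))
})

test_that("large segment means agree with high-precision summation", {
  set.seed(33)
  seg <- random_segment(n = 1001, jitter = FALSE)
  pts <- point_velocities(seg)
  sv <- segment_mean_velocity(pts, seg)
  # compensated (Kahan) summation oracle
  s <- 0; comp <- 0
  for (v in pts$v) {
    yv <- v - comp
    tv <- s + yv
    comp <- (tv - s) - yv
    s <- tv
  }
  expect_equal(sv$mean_velocity, s / length(pts$v), tolerance = 1e-12)
})

test_that("vectorized segment velocities agree with the per-segment path", {
  set.seed(12)
  spec <- tiny_spec()
  sim <- simulate_motion(spec)
  segs <- segment_velocities(sim)
  # recompute a handful of segments one at a time
  for (sid in sample(unique(sim$segment_id), 10)) {
    seg <- sim[sim$segment_id == sid, ]
    ref <- segment_mean_velocity(point_velocities(seg), seg)
    got <- segs[segs$segment_id == sid, ]
    expect_equal(got$mean_velocity, ref$mean_velocity, tolerance = 1e-12)
    expect_equal(got$n_points, ref$n_points)
    expect_equal(got$duration, ref$duration)
  }
})

test_that("velocity is invariant under rigid motions and scales with dt", {
  set.seed(55)
  random_rotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3))
    q <- qr.Q(qr_)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  for (i in 1:20) {
    seg <- random_segment(n = 40)
    base <- point_velocities(seg)$v
    rot <- random_rotation()
    shift <- rnorm(3, 0, 10)
    xyz <- as.matrix(seg[, c("x", "y", "z")]) %*% t(rot)
    moved <- seg
    moved$x <- xyz[, 1] + shift[1]
    moved$y <- xyz[, 2] + shift[2]
    moved$z <- xyz[, 3] + shift[3]
    expect_equal(point_velocities(moved)$v, base, tolerance = 1e-9)
    # doubling all time gaps halves every velocity
    slow <- seg
    slow$t <- seg$t * 2
    expect_equal(point_velocities(slow, gap_threshold = 1)$v, base / 2,
                 tolerance = 1e-9)
  }
})

test_that("context classification follows the start/between/end rule", {
  mk_day <- function(tags) {
    tibble::tibble(participant_id = "P1", sensor = "head", study_day = 1L,
                   tag = tags, t_start = seq_along(tags))
  }
  got <- classify_segment_context(mk_day(c("idle", "task", "idle", "task",
                                           "idle")))
  expect_equal(got$action_class,
               c("no_action_start_of_day", "action", "no_action_between",
                 "action", "no_action_end_of_day"))
  got <- classify_segment_context(mk_day(c("task", "task")))
  expect_equal(got$action_class, c("action", "action"))
  expect_warning(
    got <- classify_segment_context(mk_day(c("idle", "idle"))),
    "no action segment")
  expect_equal(got$action_class, rep("no_action_start_of_day", 2))
})

test_that("context classification matches the index-scan oracle on random layouts", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    tags <- sample(c("task", "idle"), n, replace = TRUE)
    day <- tibble::tibble(participant_id = "P1", sensor = "left",
                          study_day = 1L, tag = tags,
                          t_start = seq_len(n))
    got <- suppressWarnings(classify_segment_context(day))
    expect_equal(got$action_class, oracle_day_classes(tags == "task"))
  }
})

test_that("daily slope fits recover exact linear inputs", {
  mk <- function(v) {
    tibble::tibble(participant_id = "P1", sensor = "right",
                   study_day = rep(1:30, each = 2),
                   segment_id = sprintf("s%03d", 1:60), tag = "task",
                   t_start = 1, mean_velocity = v, duration = 60,
                   n_points = 100,
                   action_class = "action")
  }
  segs <- mk(0.1 + 0.003 * rep(1:30, each = 2))
  fit <- fit_daily_slope(segs)
  expect_equal(fit$slope, 0.003, tolerance = 1e-12)
  expect_equal(fit$change, 0.090, tolerance = 1e-12)
  expect_equal(fit$vr_study_day_count, 30L)
  flat <- fit_daily_slope(mk(rep(0.25, 60)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("slopes equal the closed-form OLS oracle and change = slope x days", {
  set.seed(99)
  for (i in 1:20) {
    d <- sample(1:30, 40, replace = TRUE)
    v <- 0.2 + 0.002 * d + rnorm(40, 0, 0.05)
    segs <- tibble::tibble(participant_id = "P1", sensor = "head",
                           study_day = d,
                           segment_id = sprintf("s%03d", 1:40),
                           tag = "task", t_start = 1, mean_velocity = v,
                           duration = 60, n_points = 100,
                           action_class = "action")
    fit <- fit_daily_slope(segs)
    expect_equal(fit$slope, oracle_slope(d, v), tolerance = 1e-10)
    expect_identical(fit$change, fit$slope * fit$vr_study_day_count)
  }
})

test_that("only action segments enter the regression; day count uses all", {
  segs <- tibble::tibble(
    participant_id = "P1", sensor = "head",
    study_day = c(1L, 1L, 2L, 2L, 3L),
    segment_id = sprintf("s%d", 1:5), tag = c("task", "idle", "task",
                                              "idle", "idle"),
    t_start = 1,
    mean_velocity = c(0.1, 9, 0.2, 9, 9), duration = 60, n_points = 10,
    action_class = c("action", "no_action_between", "action",
                     "no_action_between", "no_action_end_of_day"))
  fit <- fit_daily_slope(segs)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)  # from the two action rows
  expect_equal(fit$n_segments, 2L)
  expect_equal(fit$vr_study_day_count, 3L)         # day 3 has no action
})

test_that("degenerate designs are excluded with a warning", {
  segs <- tibble::tibble(participant_id = c("P1", "P1", "P2", "P2"),
                         sensor = "head", study_day = c(1L, 2L, 1L, 1L),
                         segment_id = sprintf("s%d", 1:4), tag = "task",
                         t_start = 1,
                         mean_velocity = c(0.1, 0.2, 0.1, 0.2),
                         duration = 60, n_points = 10,
                         action_class = "action")
  expect_warning(fit <- fit_daily_slope(segs), "degenerate")
  expect_equal(fit$participant_id, "P1")
  single <- segs[segs$participant_id == "P2", ]
  expect_warning(expect_error(fit_daily_slope(single), "no participant"))
})

test_that("class summary conserves counts and reports empty classes", {
  set.seed(5)
  spec <- tiny_spec()
  segs <- classify_segment_context(segment_velocities(simulate_motion(spec)))
  summ <- velocity_by_class_summary(segs)
  expect_equal(sum(summ$n), nrow(segs))
  only_action <- segs[segs$action_class == "action", ]
  s2 <- velocity_by_class_summary(only_action)
  expect_equal(sum(s2$n[s2$action_class != "action"]), 0L)
  expect_equal(sum(s2$n), nrow(only_action))
})

test_that("action segments are about the configured ratio faster than no-action", {
  spec <- cohort_spec(n_participants = 6, n_study_days = 6,
                      action_segments_per_day = 6,
                      noaction_segments_per_day = 3,
                      segment_duration_s = 1, improvement_slope_mean = 0,
                      improvement_slope_sd = 0,
                      segment_velocity_sd = 0.02,
                      action_vs_noaction_velocity_ratio = 2,
                      eda_study_days = 1, n_sham = 2, n_standardcare = 2,
                      n_activity_days = 7, seed = 17)
  segs <- classify_segment_context(segment_velocities(simulate_motion(spec)))
  summ <- velocity_by_class_summary(segs)
  for (s in unique(summ$sensor)) {
    act <- summ$mean[summ$sensor == s & summ$action_class == "action"]
    noact <- summ[summ$sensor == s & summ$action_class != "action" &
                    summ$n > 0, ]
    ratio <- act / mean(noact$mean)
    expect_lt(abs(ratio - 2) / 2, 0.1)
  }
})
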