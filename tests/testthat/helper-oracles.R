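# Independent reference implementations used to cross-check the package.
# These deliberately use naive loops / closed forms, not the package's
# code paths.

# speeds from consecutive sample pairs, one pair at a time
oracle_point_velocities <- function(seg, gap_threshold = 0.5) {
  t <- c(); v <- c()
  for (i in 2:nrow(seg)) {
    dt <- seg$t[i] - seg$t[i - 1]
    if (dt > 0 && dt <= gap_threshold) {
      dd <- sqrt((seg$x[i] - seg$x[i - 1])^2 +
                   (seg$y[i] - seg$y[i - 1])^2 +
                   (seg$z[i] - seg$z[i - 1])^2)
      t <- c(t, seg$t[i]); v <- c(v, dd / dt)
    }
  }
  list(t = t, v = v)
}

# closed-form OLS slope: sum((d - dbar)(v - vbar)) / sum((d - dbar)^2)
oracle_slope <- function(d, v) {
  sum((d - mean(d)) * (v - mean(v))) / sum((d - mean(d))^2)
}

# sort-based median and MAD, no calls into stats::median/mad
oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_mad <- function(x) oracle_median(abs(x - oracle_median(x)))

# midranks (average ties), then the product-moment formula by hand
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# index-scan classifier over one day's action flags
oracle_day_classes <- function(is_action) {
  n <- length(is_action)
  if (!any(is_action)) {
    return(rep("no_action_start_of_day", n))
  }
  first_a <- min(which(is_action)); last_a <- max(which(is_action))
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is_action[i]) "action"
      else if (i < first_a) "no_action_start_of_day"
      else if (i > last_a) "no_action_end_of_day"
      else "no_action_between"
  }
  out
}

# random motion segment with roughly 30 Hz timestamps
random_segment <- function(n = 50, jitter = TRUE) {
  dt <- rep(1 / 30, n - 1) + if (jitter) runif(n - 1, -0.005, 0.005) else 0
  tibble::tibble(
    t = cumsum(c(0, dt)),
    x = cumsum(rnorm(n, 0, 0.02)),
    y = cumsum(rnorm(n, 0, 0.02)),
    z = cumsum(rnorm(n, 0, 0.02)),
    segment_id = "seg1", sensor = "head", study_day = 1L, tag = "task"
  )
}

# a small spec that runs in well under a second; any default can be
# overridden by name
tiny_spec <- function(...) {
  args <- list(n_participants = 3, n_study_days = 4,
               action_segments_per_day = 3, noaction_segments_per_day = 3,
               segment_duration_s = 1, eda_study_days = 2,
               n_sham = 2, n_standardcare = 2, n_activity_days = 14,
               seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}
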