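test_that("segmentation splits on long gaps and sensor changes only", {
  # 13 contiguous samples -> one segment
  s <- make_samples(seq(0, 60, 5), rep(100, 13))
  expect_equal(unique(segment_by_gaps(s)$segment), 1L)

  # 25-min gap -> two segments
  s2 <- make_samples(c(0, 5, 10, 35, 40), c(100, 101, 102, 103, 104))
  seg2 <- segment_by_gaps(s2)
  expect_equal(seg2$segment, c(1L, 1L, 1L, 2L, 2L))

  # a gap of exactly 20 min does not split ("longer than" is strict)
  s3 <- make_samples(c(0, 5, 25, 30), rep(90, 4))
  expect_equal(unique(segment_by_gaps(s3)$segment), 1L)

  # sensor change splits even without a time gap
  s4 <- make_samples(seq(0, 25, 5), rep(90, 6),
                     sensor = rep(c("S1", "S2"), each = 3))
  expect_equal(segment_by_gaps(s4)$segment, rep(1:2, each = 3))

  # concatenation of segments reproduces the input
  expect_identical(seg2[, names(s2)], s2)

  expect_error(segment_by_gaps(s2[c(2, 1, 3, 4, 5), ]), "increasing")
})

test_that("short-gap interpolation is exactly linear and never extrapolates", {
  s <- make_samples(c(0, 15), c(100, 112))
  out <- interpolate_short_gaps(segment_by_gaps(s))
  expect_equal(out$glucose_mg_dl, c(100, 104, 108, 112))
  expect_equal(out$observed, c(TRUE, FALSE, FALSE, TRUE))

  s2 <- make_samples(c(0, 5, 15), c(90, 90, 90))
  expect_equal(interpolate_short_gaps(segment_by_gaps(s2))$glucose_mg_dl,
               rep(90, 4))

  # random piecewise-linear signal vs an independent two-point-line oracle
  set.seed(42)
  for (rep in 1:5) {
    knots <- cumsum(c(0, sample(c(5, 10, 15, 20), 12, replace = TRUE)))
    knots <- knots[knots <= 120]
    if (knots[length(knots)] < 120) knots <- c(knots, 120)
    vals <- runif(length(knots), 70, 180)
    out <- interpolate_short_gaps(segment_by_gaps(make_samples(knots, vals)))
    grid <- seq(0, 120, 5)
    oracle <- vapply(grid, function(g) {
      i <- max(which(knots <= g))
      if (knots[i] == g) return(vals[i])
      # brute-force two-point line through the flanking observations
      vals[i] + (vals[i + 1] - vals[i]) * (g - knots[i]) / (knots[i + 1] - knots[i])
    }, 0)
    expect_equal(out$glucose_mg_dl, oracle, tolerance = 1e-12)
  }

  # output never extends beyond segment ends
  expect_equal(range(as.numeric(out$timestamp)),
               range(as.numeric(make_samples(knots, vals)$timestamp)))
})

test_that("drift correction removes slow trends and preserves fast dynamics", {
  cfg <- preprocess_config()
  minutes <- seq(0, 3 * 1440 - 5, 5)

  # constant segment -> identically zero
  flat <- interpolate_short_gaps(segment_by_gaps(make_samples(minutes, rep(95, length(minutes)))))
  expect_equal(correct_drift(flat, cfg)$glucose_mg_dl, rep(0, nrow(flat)),
               tolerance = 1e-10)

  # spike train + linear drift 0.5 mg/dL/h: post-correction trend < 0.05 mg/dL/h
  spike <- numeric(length(minutes))
  for (m0 in (rep((0:2) * 1440, each = 3) + c(8, 13, 19) * 60))
    spike <- spike + 50 * exp(-((minutes - m0 - 45)^2) / (2 * 30^2))
  drifted <- 90 + spike + 0.5 * minutes / 60
  seg <- interpolate_short_gaps(segment_by_gaps(make_samples(minutes, drifted)))
  out <- correct_drift(seg, cfg)
  trend <- coef(lm(out$glucose_mg_dl ~ I(minutes / 60)))[2]
  expect_lt(abs(unname(trend)), 0.05)

  # sinusoidal drift (period 3 d): corrected series tracks the drift-free truth
  sin_drift <- 8 * sin(2 * pi * minutes / (3 * 1440))
  seg2 <- interpolate_short_gaps(segment_by_gaps(make_samples(minutes, 90 + spike + sin_drift)))
  out2 <- correct_drift(seg2, cfg)
  expect_gt(cor(out2$glucose_mg_dl, spike), 0.95)

  # segments too short for a windowed baseline are flagged and warned about
  short <- interpolate_short_gaps(segment_by_gaps(make_samples(seq(0, 60, 5), rep(100, 13))))
  expect_warning(res <- correct_drift(short, cfg), "too short")
  expect_true(all(res$drift_skipped))
})

test_that("stable baseline is the across-night minimum of lowest-variability windows", {
  cfg <- preprocess_config()
  minutes <- seq(0, 2 * 1440 - 5, 5)

  # flat trace -> the level itself
  flat <- make_samples(minutes, rep(90, length(minutes)))
  expect_equal(compute_stable_baseline(flat, cfg)$value, 90)

  # nights with candidate levels 88 and 84 -> 84 (minimum across nights)
  vals <- ifelse(minutes < 1440, 88, 84) + ifelse((minutes %% 1440) >= 8 * 60, 40, 0)
  two <- make_samples(minutes, vals)
  bl <- compute_stable_baseline(two, cfg)
  expect_equal(bl$value, 84)
  expect_equal(bl$source_night, as.Date("2024-01-09"))

  # exactly one noise-free overnight window at 85: exhaustive-scan oracle
  set.seed(7)
  night <- minutes < 8 * 60
  noisy <- 85 + rnorm(length(minutes), 0, 6)
  quiet_idx <- minutes >= 120 & minutes < 180  # 02:00-03:00 on night 1
  noisy[quiet_idx] <- 85
  noisy[!night] <- 130
  one_night <- make_samples(minutes[minutes < 1440], noisy[minutes < 1440])
  got <- compute_stable_baseline(one_night, cfg)
  # oracle: brute-force scan of every 1-h window in 5-min steps
  t <- as.numeric(one_night$timestamp)
  t0 <- min(t)
  best <- c(sd = Inf, mean = NA)
  for (s in seq(0, 8 * 3600 - 3600, 300)) {
    idx <- t >= t0 + s & t < t0 + s + 3600
    if (sum(idx) < 12) next
    if (sd(one_night$glucose_mg_dl[idx]) < best["sd"])
      best <- c(sd = sd(one_night$glucose_mg_dl[idx]),
                mean = mean(one_night$glucose_mg_dl[idx]))
  }
  expect_equal(got$value, unname(best["mean"]), tolerance = 1e-10)
  expect_equal(got$value, 85, tolerance = 1e-6)

  # no complete overnight window -> flagged 5th-percentile fallback
  daytime <- make_samples(seq(9 * 60, 20 * 60, 5), runif(133, 90, 160))
  fb <- compute_stable_baseline(daytime, cfg)
  expect_true(fb$fallback)
  expect_equal(fb$value, quantile(daytime$glucose_mg_dl, 0.05, names = FALSE))
})

test_that("rebaselining shifts by a constant and reconciles sensors", {
  s <- make_samples(seq(0, 20, 5), c(0, 1, -1, 2, 0))
  out <- rebaseline(s, list(value = 85))
  expect_equal(out$glucose_mg_dl - s$glucose_mg_dl, rep(85, 5))

  # two sensors with a step offset: overnight means reconcile after the chain
  set.seed(11)
  minutes <- seq(0, 4 * 1440 - 5, 5)
  base <- 88 + 30 * exp(-((minutes %% 1440 - 780)^2) / (2 * 120^2))
  offset <- ifelse(minutes < 2 * 1440, 0, 12)
  raw <- make_samples(minutes, base + offset + rnorm(length(minutes), 0, 1),
                      sensor = ifelse(minutes < 2 * 1440, "S1", "S2"))
  pre <- suppressWarnings(preprocess_cgm(raw))
  g <- pre$gridded
  hrs <- as.POSIXlt(g$timestamp, tz = "UTC")$hour
  m1 <- mean(g$glucose_mg_dl[g$sensor_id == "S1" & hrs < 8])
  m2 <- mean(g$glucose_mg_dl[g$sensor_id == "S2" & hrs < 8])
  raw_hrs <- as.POSIXlt(raw$timestamp, tz = "UTC")$hour
  r1 <- mean(raw$glucose_mg_dl[raw$sensor_id == "S1" & raw_hrs < 8])
  r2 <- mean(raw$glucose_mg_dl[raw$sensor_id == "S2" & raw_hrs < 8])
  expect_lt(abs(m1 - m2), abs(r1 - r2))
  expect_lt(abs(m1 - m2), 1.5)
})

test_that("Gaussian smoothing has unit gain, known impulse response, and reduces noise", {
  cfg <- preprocess_config()
  minutes <- seq(0, 495, 5)
  s <- interpolate_short_gaps(segment_by_gaps(make_samples(minutes, rep(100, 100))))
  expect_equal(gaussian_smooth(s, cfg)$glucose_mg_dl, rep(100, 100))

  # unit impulse: centre tap of the normalised 5-tap kernel
  imp <- rep(0, 100); imp[50] <- 1
  si <- interpolate_short_gaps(segment_by_gaps(make_samples(minutes, imp)))
  sm <- gaussian_smooth(si, cfg)
  kern <- dnorm(-2:2); kern <- kern / sum(kern)
  expect_equal(sm$glucose_mg_dl[50], kern[3], tolerance = 1e-12)
  expect_equal(sm$glucose_mg_dl[48:52], kern, tolerance = 1e-12)

  set.seed(1)
  noise <- rnorm(500, 0, 5)
  sn <- interpolate_short_gaps(segment_by_gaps(
    make_samples(seq(0, 2495, 5), 100 + noise)))
  expect_lt(sd(gaussian_smooth(sn, cfg)$glucose_mg_dl), 5)

  # delta kernel leaves the series untouched (smoothing is applied once)
  cfg1 <- preprocess_config(smooth_window = 1)
  expect_equal(gaussian_smooth(sn, cfg1)$glucose_mg_dl, sn$glucose_mg_dl)
})

test_that("gridding uses left-closed bins labelled by their left edge", {
  s <- make_samples(c(0, 5, 10), c(100, 101, 102))
  expect_equal(resample_to_grid(s)$glucose_mg_dl, c(100, 101, 102))

  # two samples in one bin are averaged
  origin <- as.POSIXct("2024-01-08 12:01:00", tz = "UTC")
  s2 <- data.frame(participant_id = "P1",
                   timestamp = origin + c(0, 120),
                   glucose_mg_dl = c(101, 103), sensor_id = "S1")
  out2 <- resample_to_grid(s2)
  expect_equal(out2$glucose_mg_dl, 102)
  expect_equal(format(out2$timestamp, "%H:%M"), "12:00")

  # 12:03 sample labelled by the 12:00 bin edge
  s3 <- data.frame(participant_id = "P1",
                   timestamp = as.POSIXct("2024-01-08 12:03:00", tz = "UTC"),
                   glucose_mg_dl = 110, sensor_id = "S1")
  expect_equal(format(resample_to_grid(s3)$timestamp, "%H:%M"), "12:00")
})

test_that("EMA alignment averages the 5-10 minute window and drops empty windows", {
  origin <- as.POSIXct("2024-01-08 12:00:00", tz = "UTC")
  grid <- data.frame(participant_id = "P1",
                     timestamp = origin + c(5, 10) * 60,
                     glucose_mg_dl = c(110, 112))
  ema <- data.frame(participant_id = "P1", timestamp = origin)
  expect_equal(align_glucose_to_ema(grid, ema)$glucose, 111)

  # only the +10 min sample present
  grid2 <- grid[2, ]
  expect_equal(align_glucose_to_ema(grid2, ema)$glucose, 112)

  # EMA during a long gap -> missing
  grid3 <- data.frame(participant_id = "P1",
                      timestamp = origin + c(60, 65) * 60,
                      glucose_mg_dl = c(100, 100))
  expect_true(is.na(align_glucose_to_ema(grid3, ema)$glucose))

  # matched window never reaches outside [t+5, t+10]
  grid4 <- data.frame(participant_id = "P1",
                      timestamp = origin + c(0, 4.9, 10.1, 15) * 60,
                      glucose_mg_dl = c(1, 2, 3, 4))
  expect_true(is.na(align_glucose_to_ema(grid4, ema)$glucose))
})

test_that("participant QC applies the concurrent-run threshold", {
  mk <- function(n_ok, n_na) data.frame(glucose = c(runif(n_ok, 80, 120),
                                                    rep(NA_real_, n_na)))
  expect_false(qc_participant(mk(19, 5))$include)
  expect_true(qc_participant(mk(22, 5))$include)
  expect_false(qc_participant(mk(0, 10))$include)
  expect_equal(qc_participant(mk(22, 5))$n_concurrent, 22)
})

test_that("pipeline conserves observed samples and never bridges long gaps", {
  p <- cohort_params(n_participants = 2, n_days = 7, seed = 31)
  co <- simulate_cohort(p)
  for (pid in unique(co$cgm$participant_id)) {
    raw <- co$cgm[co$cgm$participant_id == pid, ]
    seg <- segment_by_gaps(raw)
    grid <- interpolate_short_gaps(seg)
    # conservation: observed count unchanged by drift correction + rebaseline
    corrected <- suppressWarnings(correct_drift(grid))
    shifted <- rebaseline(corrected, list(value = 85))
    expect_equal(sum(grid$observed), nrow(raw))
    expect_equal(sum(shifted$observed), sum(grid$observed))
    # within segments the grid is contiguous; across segments gaps persist
    for (sid in unique(grid$segment)) {
      tt <- as.numeric(grid$timestamp[grid$segment == sid])
      if (length(tt) > 1) expect_true(all(diff(tt) == 300))
    }
    seg_ends <- tapply(as.numeric(grid$timestamp), grid$segment, max)
    seg_starts <- tapply(as.numeric(grid$timestamp), grid$segment, min)
    if (length(seg_ends) > 1) {
      between <- seg_starts[-1] - seg_ends[-length(seg_ends)]
      same_sensor <- tapply(grid$sensor_id, grid$segment, `[`, 1)
      splits_by_time <- same_sensor[-1] == same_sensor[-length(same_sensor)]
      expect_true(all(between[splits_by_time] > 20 * 60))
    }
  }
})
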