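test_that("generator is deterministic under a fixed seed", {
  p <- cohort_params(n_participants = 3, n_days = 4, seed = 99)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1$cgm, c2$cgm)
  expect_identical(c1$ema, c2$ema)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$truth$a, c2$truth$a)
  # EMA stream unchanged when CGM generation is skipped
  c3 <- simulate_cohort(p, include_cgm = FALSE)
  expect_identical(c1$ema, c3$ema)
})

test_that("silent generator settings give a constant trace at basal", {
  p <- quiet_params(n_participants = 1, n_days = 3, seed = 5)
  co <- simulate_cohort(p)
  expect_equal(unique(co$cgm$glucose_mg_dl), unname(co$truth$basal[1]),
               tolerance = 1e-12)
  expect_equal(nrow(co$cgm), 3 * 288)
})

test_that("overnight glucose sits below the daily mean under defaults", {
  p <- cohort_params(n_participants = 4, n_days = 14, seed = 21)
  co <- simulate_cohort(p)
  hrs <- as.POSIXlt(co$cgm$timestamp, tz = "UTC")$hour
  overnight <- hrs < 8
  # oracle: direct averaging of the generated arrays
  expect_lt(mean(co$cgm$glucose_mg_dl[overnight]),
            mean(co$cgm$glucose_mg_dl[!overnight]))
})

test_that("generated values respect physical bounds", {
  co <- simulate_cohort(cohort_params(n_participants = 5, n_days = 10, seed = 3))
  expect_true(all(co$cgm$glucose_mg_dl >= 40 & co$cgm$glucose_mg_dl <= 250))
  vas <- unlist(co$ema[c("happy", "sad", "hunger", "satiety")])
  expect_true(all(vas >= 0 & vas <= 100))
})

test_that("EMA schedule matches the study design", {
  # no missingness: exactly 2 x 28 records per participant
  p0 <- cohort_params(n_participants = 3, seed = 8, ema_miss_rate = 0)
  co0 <- simulate_cohort(p0, include_cgm = FALSE)
  expect_equal(as.vector(table(co0$ema$participant_id)), rep(56L, 3))

  # default missingness: mean near 48 per participant
  p1 <- cohort_params(n_participants = 30, seed = 8)
  co1 <- simulate_cohort(p1, include_cgm = FALSE)
  expect_equal(nrow(co1$ema) / 30, 48, tolerance = 0.05)

  # same-day assessments at least the minimum gap apart, inside wake hours
  lt <- as.POSIXlt(co1$ema$timestamp, tz = "UTC")
  hour <- lt$hour + lt$min / 60
  expect_true(all(hour >= p1$wake_start & hour <= p1$wake_end))
  day_key <- paste(co1$ema$participant_id, as.Date(co1$ema$timestamp, tz = "UTC"))
  gaps <- tapply(hour, day_key, function(h) if (length(h) > 1) min(diff(sort(h))) else Inf)
  expect_true(all(gaps >= p1$ema_min_gap))
})

test_that("metabolic composite slope converges to the generative coupling", {
  # near-noiseless latent chain: OLS of the composite on true standardised
  # glucose recovers met_scale * a_i
  p <- cohort_params(n_participants = 4, n_days = 28, seed = 13,
                     met_noise_sd = 0.01, item_noise_sd = 0.01,
                     ema_miss_rate = 0)
  co <- simulate_cohort(p, include_cgm = FALSE)
  ema <- compute_composites(co$truth$ema)
  for (pid in names(co$truth$a)) {
    d <- ema[ema$participant_id == pid, ]
    slope <- coef(lm(metabolic_state ~ z_glucose_true, data = d))[2]
    expect_equal(unname(slope) / p$met_scale, unname(co$truth$a[pid]),
                 tolerance = 0.05)
  }
})

test_that("mood-on-glucose regression recovers the product of paths", {
  # a = -0.5 exactly, b = -3, c' = 0 -> slope of mood on z(glucose) ~ 1.5;
  # oracle = ordinary least squares on the generated records
  p <- cohort_params(n_participants = 40, n_days = 28, seed = 17,
                     a_sd = 0, ema_miss_rate = 0,
                     met_between_sd = 0, mood_between_sd = 0)
  co <- simulate_cohort(p, include_cgm = FALSE)
  ema <- compute_composites(co$truth$ema)
  slope <- coef(lm(mood_state ~ z_glucose_true, data = ema))[2]
  expect_equal(unname(slope), 1.5, tolerance = 0.5)

  # no glucose pathway: a = 0, c' = 0 -> correlation ~ 0
  p0 <- cohort_params(n_participants = 40, n_days = 28, seed = 18,
                      a_mean = 0, a_sd = 0, a_trunc = c(-0.5, 0.5),
                      c_prime = 0, ema_miss_rate = 0)
  co0 <- simulate_cohort(p0, include_cgm = FALSE)
  ema0 <- compute_composites(co0$truth$ema)
  expect_lt(abs(cor(ema0$glucose_clean, ema0$mood_state)), 0.1)
})

test_that("cohort composition and plumbing behave as configured", {
  co <- simulate_cohort(cohort_params(n_participants = 90, n_days = 1, seed = 2),
                        include_cgm = FALSE)
  expect_equal(as.vector(table(co$participants$sex)), c(46L, 44L))
  expect_equal(nrow(co$participants), 90)

  # minimal bundle runs end to end through the generator
  mini <- simulate_cohort(cohort_params(n_participants = 1, n_days = 1, seed = 4))
  expect_equal(nrow(mini$participants), 1)
  expect_gt(nrow(mini$cgm), 0)
  expect_true(is.finite(mini$truth$acme))

  # additivity of the implied true decomposition
  expect_identical(mini$truth$acme + mini$truth$ade, mini$truth$total)
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_params(meal_rise_tau = -5))
  expect_error(cohort_params(ar_coef = 1.2))
  expect_error(cohort_params(ema_min_gap = 8, wake_start = 8, wake_end = 15))
})
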