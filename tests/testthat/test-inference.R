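make_aligned <- function(seed, n = 20, days = 28, ...) {
  co <- simulate_cohort(cohort_params(n_participants = n, n_days = days,
                                      seed = seed, ...), include_cgm = FALSE)
  list(aligned = aligned_from_truth(co), cohort = co)
}

test_that("mixed models refuse single-participant data", {
  d <- make_aligned(1, n = 6)$aligned
  one <- d[d$participant_id == d$participant_id[1], ]
  expect_error(
    fit_lme(lme_spec("mood_state", "z_ln_glucose", "z_ln_glucose"), one),
    "at least 2 participants")
})

test_that("a random slope must also be a fixed effect", {
  expect_error(lme_spec("mood_state", "z_ln_glucose", "z_metabolic_state"),
               "fixed effect")
})

test_that("identical coupling yields near-identical accuracy scores", {
  d <- make_aligned(12, n = 12, a_sd = 0, met_noise_sd = 0.3)$aligned
  sc <- interoceptive_accuracy(d)
  expect_equal(nrow(sc), 12)
  expect_lt(sd(sc$accuracy), 0.08)
  expect_true(all(sc$accuracy > 0))  # negative coupling inverts to positive
})

test_that("accuracy ranks participants by their true coupling", {
  res <- make_aligned(23, n = 30, a_dist = "uniform")
  sc <- interoceptive_accuracy(res$aligned)
  truth <- res$cohort$truth$a[sc$participant_id]
  expect_gt(cor(sc$accuracy, -truth, method = "spearman"), 0.5)
  # the strongest coupling scores above the weakest
  expect_gt(sc$accuracy[which.min(truth)], sc$accuracy[which.max(truth)])
  # reverse-direction variant runs and also orders by coupling
  sc_rev <- interoceptive_accuracy(res$aligned,
                                   direction = "metabolic_to_glucose")
  expect_gt(cor(sc_rev$accuracy, -truth, method = "spearman"), 0.4)
})

test_that("mood summaries use the sample definition and track true noise", {
  d <- data.frame(participant_id = rep(c("A", "B"), c(2, 3)),
                  mood_state = c(-50, 50, 10, 10, 10))
  ms <- mood_summary(d)
  expect_equal(ms$mood_mean, c(0, 10))
  expect_equal(ms$mood_sd, c(70.71068, 0), tolerance = 1e-5)

  res <- make_aligned(31, n = 30)
  ms2 <- mood_summary(res$aligned)
  truth_sd <- res$cohort$truth$mood_noise_sd[ms2$participant_id]
  expect_gt(cor(ms2$mood_sd, truth_sd, method = "spearman"), 0.5)
})

test_that("participant-level models fit and reject degenerate inputs", {
  res <- make_aligned(41, n = 30)
  sc <- interoceptive_accuracy(res$aligned)
  ms <- mood_summary(res$aligned)
  pts <- derive_indices(res$cohort$participants)
  fits <- accuracy_models(sc, ms, pts)
  expect_s3_class(fits$mood_sd, "lm")
  # generator couples mood noise to coupling strength: negative sign expected
  expect_lt(coef(fits$mood_sd)[["z_accuracy"]], 0)
  # mood *level* is generated independently of accuracy: no association
  expect_gt(summary(fits$mood_mean)$coefficients["z_accuracy", 4], 0.05)
  expect_true("accuracy" %in% names(fits))

  sc$accuracy <- 0.4  # no variance in the predictor
  expect_error(accuracy_models(sc, ms, pts), "z-standardise")
})

test_that("sensitivity refits are identity when nobody is excluded", {
  res <- make_aligned(51, n = 14, bmi_mean = 23, bmi_sd = 1.5,
                      bmi_range = c(18, 27))
  pts <- derive_indices(res$cohort$participants)
  out <- sensitivity_refit(res$aligned, pts, exclusion = "bmi",
                           n_sims = 1000, seed = 3)
  expect_equal(length(out$excluded_ids), 0)
  expect_equal(out$n_subset, 14)
  expect_equal(out$deltas$delta, rep(0, nrow(out$deltas)))

  # exclusion leaves the complement and errors below the floor
  med_bmi <- median(pts$bmi)
  out2 <- sensitivity_refit(res$aligned, pts, exclusion = "bmi",
                            bmi_threshold = med_bmi, n_sims = 1000, seed = 3,
                            min_remaining = 2)
  expect_equal(out2$n_subset, 14 - sum(pts$bmi >= med_bmi))
  expect_error(sensitivity_refit(res$aligned, pts, exclusion = "bmi",
                                 bmi_threshold = 18), "leaves only")
})

test_that("fallback ladder keeps the fixed-effect specification intact", {
  d <- make_aligned(61, n = 15)$aligned
  fit <- fit_lme(lme_spec("mood_state", "z_ln_glucose + z_metabolic_state",
                          c("z_ln_glucose", "z_metabolic_state")), d)
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "z_ln_glucose", "z_metabolic_state"))
  expect_true(fit$fallback %in% c("none", "uncorrelated", "intercept"))
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_hi))
  v <- fit$vcov_fixed
  expect_equal(v, t(v), tolerance = 1e-10)
  expect_true(all(eigen(v, only.values = TRUE)$values > -1e-12))
})
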