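#' @importFrom stats rnorm runif rlnorm rpois sd quantile median approx
#'   setNames filter qt pt qnorm pnorm cor coef vcov resid complete.cases
#'   as.formula terms lm splinefun dnorm
NULL

# normalised bi-exponential meal excursion, peak 1 at its mode
biexp_excursion <- function(dt, rise_tau, decay_tau) {
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  norm <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  (exp(-dt / decay_tau) - exp(-dt / rise_tau)) / norm
}

#' Noise- and drift-free glucose signal of one simulated participant
#'
#' Basal level plus a non-negative daytime circadian elevation plus the sum of
#' bi-exponential meal excursions. Overnight (roughly 00:00-06:00) the signal
#' sits at the participant's basal level, which is what the stable-baseline
#' stage of the preprocessing chain is meant to recover.
#'
#' @param minutes Times in minutes since study start (day 1, 00:00).
#' @param profile One participant profile (a row-list from
#'   [simulate_cohort()]'s internal profile table).
#' @param params A [cohort_params()] object.
#' @return Glucose values, mg/dL.
#' @export
clean_glucose_values <- function(minutes, profile, params) {
  hours <- (minutes / 60) %% 24
  dist <- abs(hours - params$circadian_peak)
  dist <- pmin(dist, 24 - dist)
  g <- profile$basal +
    params$circadian_amplitude * exp(-0.5 * (dist / params$circadian_width)^2)
  mt <- profile$meal_minutes
  amps <- profile$meal_amps
  horizon <- 8 * params$meal_decay_tau
  for (j in seq_along(mt)) {
    idx <- which(minutes >= mt[j] & minutes <= mt[j] + horizon)
    if (!length(idx)) next
    g[idx] <- g[idx] +
      amps[j] * biexp_excursion(minutes[idx] - mt[j], params$meal_rise_tau,
                                params$meal_decay_tau)
  }
  g
}

# smooth per-sensor calibration drift: random cubic rescaled to [0, amplitude]
drift_curve <- function(u, coefs, amplitude) {
  s <- coefs[1] + coefs[2] * u + coefs[3] * u^2 + coefs[4] * u^3
  rng <- max(s) - min(s)
  if (rng < 1e-12 || amplitude == 0) return(rep(0, length(u)))
  (s - min(s)) / rng * amplitude
}

# participant-level draws: demographics, labs, signal shape, latent couplings.
# consumes the master RNG stream; call under set.seed().
make_profiles <- function(params) {
  n <- params$n_participants
  n_female <- round(n * params$sex_female_prop)
  sex <- c(rep("female", n_female), rep("male", n - n_female))
  age <- pmin(pmax(rnorm(n, params$age_mean, params$age_sd),
                   params$age_range[1]), params$age_range[2])
  bmi <- pmin(pmax(rnorm(n, params$bmi_mean, params$bmi_sd),
                   params$bmi_range[1]), params$bmi_range[2])
  basal <- rnorm(n, params$basal_mean, params$basal_sd)
  a <- if (params$a_dist == "uniform") {
    runif(n, params$a_range[1], params$a_range[2])
  } else {
    pmin(pmax(rnorm(n, params$a_mean, params$a_sd),
              params$a_trunc[1]), params$a_trunc[2])
  }
  met_center <- rnorm(n, params$met_center, params$met_between_sd)
  mood_center <- rnorm(n, params$mood_center, params$mood_between_sd)
  mood_noise_sd <- params$mood_noise_sd_base +
    params$mood_noise_accuracy_coupling * (1 - pmin(abs(a), 1))

  n_meals <- length(params$meal_times)
  n_sensors <- if (params$n_days > params$sensor_swap_day) 2L else 1L

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    meal_minutes <- rep((seq_len(params$n_days) - 1) * 1440, each = n_meals) +
      rep(params$meal_times * 60, params$n_days) +
      rnorm(params$n_days * n_meals, 0, params$meal_jitter_sd * 60)
    meal_amps <- pmax(rnorm(length(meal_minutes), params$meal_amplitude,
                            params$meal_amplitude * params$meal_amp_cv), 0)
    drift_coefs <- matrix(rnorm(4 * n_sensors), nrow = n_sensors)
    # calibration bias is non-negative in this generator (as is the drift),
    # so the across-night overnight minimum remains anchored at basal
    sensor_offset <- if (n_sensors > 1) abs(rnorm(1, 0, params$sensor_offset_sd)) else 0

    n_draws <- sample(c(1L, 2L, 3L), 1, prob = c(0.10, 0.011, 0.889))
    fg <- rnorm(3, basal[i] - 2, 3)
    ins_med <- rlnorm(1, params$insulin_meanlog, params$insulin_sdlog)
    ins <- rlnorm(3, log(ins_med), 0.15)
    tg_med <- rlnorm(1, params$tg_meanlog, params$tg_sdlog)
    tg <- rlnorm(3, log(tg_med), 0.12)
    if (n_draws < 3) {
      drop <- (n_draws + 1):3
      fg[drop] <- NA_real_; ins[drop] <- NA_real_; tg[drop] <- NA_real_
    }

    profiles[[i]] <- list(
      participant_id = sprintf("P%03d", i),
      sex = sex[i], age = age[i], bmi = bmi[i],
      basal = basal[i], a = a[i],
      met_center = met_center[i], mood_center = mood_center[i],
      mood_noise_sd = mood_noise_sd[i],
      meal_minutes = meal_minutes, meal_amps = meal_amps,
      drift_coefs = drift_coefs, sensor_offset = sensor_offset,
      fasting_glucose = fg, fasting_insulin = ins, triglycerides = tg
    )
  }
  profiles
}

study_epoch <- function(params) {
  as.POSIXct(paste(params$start_date, "00:00:00"), tz = "UTC")
}

#' Simulate one participant's raw CGM trace
#'
#' Samples on a regular grid over the study, as the sum of the clean
#' physiological signal ([clean_glucose_values()]), a smooth non-negative
#' per-sensor calibration drift, a step offset for the replacement sensor, and
#' AR(1) measurement noise; values are clamped to the sensor's reporting range
#' of 40-250 mg/dL. Short (1-3 samples) and long (> 20 min) dropouts are then
#' deleted at the configured daily rates, and the sensor identifier switches at
#' the swap day.
#'
#' @param profile Participant profile (see [simulate_cohort()]).
#' @param params A [cohort_params()] object.
#' @param seed Integer seed for the noise and gap draws.
#' @return A data frame with columns `participant_id`, `timestamp` (POSIXct,
#'   device clock stored as UTC), `glucose_mg_dl`, `sensor_id`, plus a hidden
#'   column `minute` (minutes since study start) used internally.
#' @export
simulate_glucose_trace <- function(profile, params, seed = 1L) {
  validate_cohort_params(params)
  set.seed(seed)
  minutes <- seq(0, params$n_days * 1440 - params$grid_step, by = params$grid_step)
  n <- length(minutes)
  clean <- clean_glucose_values(minutes, profile, params)

  swap_min <- params$sensor_swap_day * 1440
  sensor_idx <- ifelse(minutes < swap_min, 1L, 2L)
  n_sensors <- max(sensor_idx)
  drift <- numeric(n)
  for (s in seq_len(n_sensors)) {
    idx <- which(sensor_idx == s)
    u <- (minutes[idx] - minutes[idx][1]) /
      max(minutes[idx][length(idx)] - minutes[idx][1], 1)
    drift[idx] <- drift_curve(u, profile$drift_coefs[s, ], params$drift_amplitude)
    if (s == 2L) drift[idx] <- drift[idx] + profile$sensor_offset
  }

  innov_sd <- params$noise_sd * sqrt(1 - params$ar_coef^2)
  noise <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), params$ar_coef,
                                    method = "recursive",
                                    init = rnorm(1, 0, params$noise_sd)))
  glucose <- pmin(pmax(clean + drift + noise, 40), 250)

  keep <- rep(TRUE, n)
  n_short <- rpois(1, params$short_gap_rate * params$n_days)
  if (n_short > 0) {
    for (k in seq_len(n_short)) {
      start <- sample.int(n, 1)
      len <- sample(1:3, 1)
      keep[start:min(start + len - 1L, n)] <- FALSE
    }
  }
  n_long <- rpois(1, params$long_gap_rate * params$n_days)
  if (n_long > 0) {
    for (k in seq_len(n_long)) {
      start <- sample.int(n, 1)
      dur_min <- runif(1, params$long_gap_hours[1], params$long_gap_hours[2]) * 60
      len <- max(ceiling(dur_min / params$grid_step), 5L)
      keep[start:min(start + len - 1L, n)] <- FALSE
    }
  }

  out <- data.frame(
    participant_id = profile$participant_id,
    timestamp = study_epoch(params) + minutes * 60,
    glucose_mg_dl = glucose,
    sensor_id = paste0(profile$participant_id, "_S", sensor_idx),
    minute = minutes,
    stringsAsFactors = FALSE
  )
  out[keep, , drop = FALSE]
}

# EMA schedule: `ema_per_day` wake-hour assessments per day, sequentially
# drawn so consecutive same-day assessments are >= ema_min_gap hours apart,
# then thinned at the missingness rate.
simulate_ema_times <- function(profile, params, seed) {
  set.seed(seed)
  k <- params$ema_per_day
  gap <- params$ema_min_gap
  times <- numeric(0)
  for (d in seq_len(params$n_days)) {
    prev <- -Inf
    for (j in seq_len(k)) {
      lo <- max(params$wake_start, prev + gap + 2 / 60)
      hi <- params$wake_end - (k - j) * (gap + 2 / 60)
      if (lo > hi) lo <- hi
      t_j <- runif(1, lo, hi)
      times <- c(times, (d - 1) * 1440 + t_j * 60)
      prev <- t_j
    }
  }
  # whole-minute timestamps (app-style logging); the schedule leaves a
  # 2-minute margin above the minimum gap so rounding cannot undercut it
  times <- round(times)
  times[runif(length(times)) >= params$ema_miss_rate]
}

# latent metabolic state and mood at given times, mapped to VAS items
simulate_ema_ratings <- function(minutes, profile, params, seed,
                                 glucose_center, glucose_scale) {
  set.seed(seed)
  n <- length(minutes)
  g_clean <- clean_glucose_values(minutes, profile, params)
  zg <- (g_clean - glucose_center) / glucose_scale
  m <- profile$a * zg + rnorm(n, 0, params$met_noise_sd)
  met_target <- profile$met_center + params$met_scale * m
  mood_latent <- profile$mood_center + params$c_prime * zg + params$b * m +
    rnorm(n, 0, profile$mood_noise_sd)
  clip01 <- function(x) pmin(pmax(x, 0), 100)
  hunger <- clip01((100 + met_target) / 2 + rnorm(n, 0, params$item_noise_sd))
  satiety <- clip01((100 - met_target) / 2 + rnorm(n, 0, params$item_noise_sd))
  happy <- clip01((100 + mood_latent) / 2 + rnorm(n, 0, params$item_noise_sd))
  sad <- clip01((100 - mood_latent) / 2 + rnorm(n, 0, params$item_noise_sd))
  data.frame(
    participant_id = profile$participant_id,
    timestamp = study_epoch(params) + minutes * 60,
    happy = happy, sad = sad, hunger = hunger, satiety = satiety,
    minute = minutes,
    glucose_clean = g_clean, z_glucose_true = zg,
    metabolic_latent = m, mood_latent = mood_latent,
    stringsAsFactors = FALSE
  )
}

#' Simulate one participant's EMA record stream
#'
#' Draws assessment times (twice daily in wake hours, at least the configured
#' minimum gap apart, thinned by the missingness rate), evaluates the latent
#' glucose -> metabolic state -> mood chain at those times using the clean
#' glucose signal, and maps the latents onto 0-100 visual-analogue items
#' (hunger/satiety and happy/sad as anti-correlated pairs).
#'
#' @param profile Participant profile.
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @param glucose_center,glucose_scale Standardisation of the clean glucose
#'   signal used by the latent model. Defaults to the mean/SD of the
#'   participant's clean trace over the full study grid; [simulate_cohort()]
#'   passes cohort-level values computed at the drawn EMA times instead.
#' @return Data frame of EMA records including ground-truth latent columns
#'   (`glucose_clean`, `z_glucose_true`, `metabolic_latent`, `mood_latent`).
#' @export
simulate_ema <- function(profile, params, seed = 1L,
                         glucose_center = NULL, glucose_scale = NULL) {
  validate_cohort_params(params)
  seeds <- derive_seeds(seed, 2)
  minutes <- simulate_ema_times(profile, params, seeds[1])
  if (is.null(glucose_center) || is.null(glucose_scale)) {
    grid <- seq(0, params$n_days * 1440 - params$grid_step, by = params$grid_step)
    clean <- clean_glucose_values(grid, profile, params)
    glucose_center <- mean(clean)
    glucose_scale <- sd(clean)
  }
  simulate_ema_ratings(minutes, profile, params, seeds[2],
                       glucose_center, glucose_scale)
}

#' Simulate a full CGM + EMA cohort with known ground truth
#'
#' Generates per-participant profiles (demographics, fasting labs, signal
#' shape, latent couplings), CGM traces, EMA streams, and a participant table,
#' together with the ground truth needed for recovery tests: the
#' per-participant glucose -> metabolic-state couplings \eqn{a_i}, the global
#' paths \eqn{b} and \eqn{c'}, the implied true indirect effect
#' \eqn{\mathrm{mean}(a_i) b}, per-participant basal levels, and the clean
#' (drift- and noise-free) traces.
#'
#' The latent glucose predictor is standardised with the cohort-level mean/SD
#' of the clean glucose signal evaluated at the drawn EMA times, so the
#' generative slopes are on the same scale as slopes fitted downstream on
#' observation-level standardised glucose.
#'
#' @param params A [cohort_params()] object.
#' @param include_cgm If `FALSE`, skip CGM trace generation (noise, drift and
#'   gap draws) and return only EMA, participants and truth. The EMA stream is
#'   unchanged because every component has its own RNG sub-stream.
#' @return A list of class `glyco_cohort` with elements `cgm`, `ema`
#'   (public columns only), `participants`, `truth`, `params`.
#' @export
simulate_cohort <- function(params = cohort_params(), include_cgm = TRUE) {
  validate_cohort_params(params)
  n <- params$n_participants
  seeds <- derive_seeds(params$seed, 1 + 3 * n)
  seed_profiles <- seeds[1]
  trace_seeds <- seeds[1 + seq_len(n)]
  time_seeds <- seeds[1 + n + seq_len(n)]
  rating_seeds <- seeds[1 + 2 * n + seq_len(n)]

  set.seed(seed_profiles)
  profiles <- make_profiles(params)

  ema_minutes <- lapply(seq_len(n), function(i)
    simulate_ema_times(profiles[[i]], params, time_seeds[i]))
  ema_clean <- lapply(seq_len(n), function(i)
    clean_glucose_values(ema_minutes[[i]], profiles[[i]], params))
  all_clean <- unlist(ema_clean)
  g_center <- mean(all_clean)
  g_scale <- sd(all_clean)
  if (!is.finite(g_scale) || g_scale == 0) g_scale <- 1

  ema_list <- lapply(seq_len(n), function(i)
    simulate_ema_ratings(ema_minutes[[i]], profiles[[i]], params,
                         rating_seeds[i], g_center, g_scale))
  ema_full <- do.call(rbind, ema_list)
  public_cols <- c("participant_id", "timestamp", "happy", "sad",
                   "hunger", "satiety")
  ema <- ema_full[, public_cols]

  cgm <- NULL
  clean_traces <- NULL
  if (include_cgm) {
    grid <- seq(0, params$n_days * 1440 - params$grid_step, by = params$grid_step)
    cgm_list <- lapply(seq_len(n), function(i)
      simulate_glucose_trace(profiles[[i]], params, trace_seeds[i]))
    cgm <- do.call(rbind, cgm_list)
    rownames(cgm) <- NULL
    clean_traces <- data.frame(
      participant_id = rep(vapply(profiles, `[[`, "", "participant_id"),
                           each = length(grid)),
      minute = rep(grid, n),
      glucose_clean = unlist(lapply(profiles, function(p)
        clean_glucose_values(grid, p, params))),
      stringsAsFactors = FALSE
    )
    cgm <- cgm[, c("participant_id", "timestamp", "glucose_mg_dl",
                   "sensor_id", "minute")]
  }

  participants <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      participant_id = p$participant_id, sex = p$sex,
      age = p$age, bmi = p$bmi,
      fasting_glucose_1 = p$fasting_glucose[1],
      fasting_glucose_2 = p$fasting_glucose[2],
      fasting_glucose_3 = p$fasting_glucose[3],
      fasting_insulin_1 = p$fasting_insulin[1],
      fasting_insulin_2 = p$fasting_insulin[2],
      fasting_insulin_3 = p$fasting_insulin[3],
      triglycerides_1 = p$triglycerides[1],
      triglycerides_2 = p$triglycerides[2],
      triglycerides_3 = p$triglycerides[3],
      stringsAsFactors = FALSE
    )
  }))
  rownames(participants) <- NULL

  ids <- vapply(profiles, `[[`, "", "participant_id")
  a_vec <- setNames(vapply(profiles, `[[`, 0, "a"), ids)
  truth <- list(
    a = a_vec,
    b = params$b,
    c_prime = params$c_prime,
    acme = mean(a_vec) * params$b,
    ade = params$c_prime,
    total = mean(a_vec) * params$b + params$c_prime,
    basal = setNames(vapply(profiles, `[[`, 0, "basal"), ids),
    mood_noise_sd = setNames(vapply(profiles, `[[`, 0, "mood_noise_sd"), ids),
    drift = setNames(lapply(profiles, function(p)
      list(coefs = p$drift_coefs, sensor_offset = p$sensor_offset)), ids),
    glucose_center = g_center,
    glucose_scale = g_scale,
    ema = ema_full,
    clean_traces = clean_traces
  )

  structure(list(cgm = cgm, ema = ema, participants = participants,
                 truth = truth, params = params),
            class = "glyco_cohort")
}

#' @export
print.glyco_cohort <- function(x, ...) {
  cat("Synthetic CGM/EMA cohort:", x$params$n_participants, "participants,",
      x$params$n_days, "days\n")
  if (!is.null(x$cgm))
    cat("  CGM samples:", nrow(x$cgm), "\n")
  cat("  EMA records:", nrow(x$ema),
      sprintf("(%.1f per participant)\n",
              nrow(x$ema) / x$params$n_participants))
  cat(sprintf("  true indirect effect mean(a)*b = %.3f, direct c' = %.3f\n",
              x$truth$acme, x$truth$ade))
  invisible(x)
}
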