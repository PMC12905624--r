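#' Parameters for the synthetic CGM + EMA cohort generator
#'
#' Bundles every knob of the simulated study: cohort composition, the shape of
#' the interstitial glucose signal (basal level, daytime circadian elevation,
#' meal excursions, per-sensor drift, autocorrelated sensor noise, data gaps),
#' the ecological momentary assessment (EMA) sampling scheme, and the latent
#' glucose -> metabolic-state -> mood structure whose path coefficients serve
#' as ground truth for recovery tests.
#'
#' The latent structure is linear with no treatment-mediator interaction: for
#' participant \eqn{i} at assessment time \eqn{t},
#' \deqn{m_{it} = a_i z_{it} + e^m_{it}, \quad
#'       y_{it} = c' z_{it} + b\, m_{it} + e^y_{it},}
#' where \eqn{z} is the standardised (noise-free) glucose level, \eqn{m} the
#' latent metabolic state (positive = hungry) and \eqn{y} the latent mood, both
#' later mapped affinely onto 0-100 visual-analogue items. The implied true
#' indirect effect is \eqn{\mathrm{mean}(a_i)\, b} and the true direct effect
#' is \eqn{c'}.
#'
#' @param n_participants Number of participants.
#' @param n_days Study duration in days.
#' @param grid_step CGM sampling interval, minutes.
#' @param basal_mean,basal_sd Between-person distribution of the overnight
#'   fasting (basal) glucose level, mg/dL.
#' @param meal_times Scheduled meal clock hours (jittered per day).
#' @param meal_jitter_sd SD of the per-day meal-time jitter, hours.
#' @param meal_amplitude Mean peak meal excursion, mg/dL.
#' @param meal_amp_cv Coefficient of variation of per-meal amplitudes.
#' @param meal_rise_tau,meal_decay_tau Rise and decay time constants of the
#'   bi-exponential meal excursion, minutes.
#' @param circadian_amplitude Peak of the daytime (non-negative) circadian
#'   elevation, mg/dL; zero overnight so the fasting trough sits at basal.
#' @param circadian_peak,circadian_width Clock hour of the circadian peak and
#'   Gaussian width (hours) of the daytime bump.
#' @param drift_amplitude Range of the smooth per-sensor calibration drift,
#'   mg/dL. Each sensor gets a random cubic drift curve rescaled to
#'   \[0, drift_amplitude\], so its minimum over the wear period is zero.
#' @param sensor_offset_sd Scale (half-normal) of the non-negative step offset
#'   applied to the replacement sensor; like the drift, a calibration bias.
#' @param noise_sd Stationary SD of the AR(1) measurement noise, mg/dL. The
#'   default reflects a factory-filtered sensor stream rather than raw
#'   electrode current.
#' @param ar_coef AR(1) coefficient of the measurement noise, |ar_coef| < 1.
#' @param short_gap_rate Expected short dropouts (1-3 missing samples, i.e.
#'   gaps <= 20 min) per day.
#' @param long_gap_rate Expected long outages (> 20 min) per day.
#' @param long_gap_hours Range of long-outage durations, hours.
#' @param sensor_swap_day Day index at which the sensor is replaced.
#' @param a_mean,a_sd Between-person distribution of the glucose ->
#'   metabolic-state coupling \eqn{a_i} (standardised units; negative:
#'   higher glucose, less hunger).
#' @param a_dist Either `"normal"` (truncated to `a_trunc`) or `"uniform"`
#'   over `a_range`.
#' @param a_range,a_trunc Support of the uniform variant / truncation bounds
#'   of the normal variant for \eqn{a_i}.
#' @param b Metabolic-state -> mood slope (mood VAS-difference units per unit
#'   latent metabolic state).
#' @param c_prime Direct glucose -> mood slope (indirect-only mediation when 0).
#' @param met_noise_sd SD of the latent metabolic-state noise \eqn{e^m}.
#' @param met_center,met_between_sd Mean and between-person SD of the
#'   metabolic-state composite (hunger - satiety scale, -100..100).
#' @param met_scale VAS-difference units per unit latent metabolic state.
#' @param mood_center,mood_between_sd Mean and between-person SD of the mood
#'   composite (happy - sad scale).
#' @param mood_noise_sd_base,mood_noise_accuracy_coupling Momentary mood noise
#'   SD is `mood_noise_sd_base + mood_noise_accuracy_coupling * (1 - |a_i|)`,
#'   so participants whose ratings track glucose closely fluctuate less.
#' @param item_noise_sd SD of the per-item VAS response noise.
#' @param ema_per_day Scheduled assessments per day.
#' @param ema_min_gap Minimum spacing between same-day assessments, hours.
#' @param ema_miss_rate Probability that a scheduled assessment is skipped.
#' @param wake_start,wake_end Clock hours bounding the EMA sampling window.
#' @param sex_female_prop Proportion of female participants (assigned
#'   deterministically by rounding, e.g. 46/90).
#' @param age_mean,age_sd,age_range Age distribution, years.
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution, kg/m^2.
#' @param insulin_meanlog,insulin_sdlog Log-normal parameters of the
#'   between-person median fasting insulin, mU/L.
#' @param tg_meanlog,tg_sdlog Log-normal parameters of fasting triglycerides,
#'   mg/dL.
#' @param start_date Calendar date of study day 1 (midnight, device clock).
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 90,
                          n_days = 28,
                          grid_step = 5,
                          basal_mean = 85,
                          basal_sd = 7,
                          meal_times = c(8, 13, 19),
                          meal_jitter_sd = 0.75,
                          meal_amplitude = 45,
                          meal_amp_cv = 0.25,
                          meal_rise_tau = 20,
                          meal_decay_tau = 60,
                          circadian_amplitude = 7,
                          circadian_peak = 15,
                          circadian_width = 4,
                          drift_amplitude = 8,
                          sensor_offset_sd = 4,
                          noise_sd = 1.5,
                          ar_coef = 0.3,
                          short_gap_rate = 2,
                          long_gap_rate = 0.15,
                          long_gap_hours = c(1, 8),
                          sensor_swap_day = 14,
                          a_mean = -0.5,
                          a_sd = 0.15,
                          a_dist = c("normal", "uniform"),
                          a_range = c(-0.9, -0.1),
                          a_trunc = c(-0.95, -0.05),
                          b = -3,
                          c_prime = 0,
                          met_noise_sd = 0.85,
                          met_center = -28,
                          met_between_sd = 12,
                          met_scale = 15,
                          mood_center = 36,
                          mood_between_sd = 20,
                          mood_noise_sd_base = 12,
                          mood_noise_accuracy_coupling = 12,
                          item_noise_sd = 2,
                          ema_per_day = 2,
                          ema_min_gap = 2,
                          ema_miss_rate = 0.145,
                          wake_start = 8,
                          wake_end = 23,
                          sex_female_prop = 46 / 90,
                          age_mean = 24.3,
                          age_sd = 3.6,
                          age_range = c(18, 34),
                          bmi_mean = 24.7,
                          bmi_sd = 4.1,
                          bmi_range = c(18, 36.7),
                          insulin_meanlog = log(7.5),
                          insulin_sdlog = 0.45,
                          tg_meanlog = log(110),
                          tg_sdlog = 0.35,
                          start_date = "2024-01-08",
                          seed = 1L) {
  a_dist <- match.arg(a_dist)
  p <- as.list(environment())
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  stopifnot(
    p$n_participants >= 1,
    p$n_days >= 1,
    p$grid_step > 0,
    p$meal_rise_tau > 0,
    p$meal_decay_tau > 0,
    p$meal_rise_tau != p$meal_decay_tau,
    abs(p$ar_coef) < 1,
    p$noise_sd >= 0,
    p$drift_amplitude >= 0,
    p$ema_per_day >= 1,
    p$ema_min_gap > 0,
    p$ema_miss_rate >= 0 && p$ema_miss_rate < 1,
    p$wake_start < p$wake_end,
    p$sensor_swap_day > 0
  )
  if (p$ema_per_day > 1) {
    span <- p$wake_end - p$wake_start
    if (span < p$ema_min_gap * (p$ema_per_day - 1))
      stop("wake window too short for ", p$ema_per_day,
           " assessments spaced >= ", p$ema_min_gap, " h apart")
  }
  invisible(p)
}

#' Configuration of the CGM preprocessing chain
#'
#' @param max_gap Gaps strictly longer than this (minutes) split the record
#'   into independent segments; shorter gaps are linearly interpolated.
#' @param grid_step Target grid spacing, minutes.
#' @param smooth_window Gaussian smoothing window length in samples (odd).
#' @param smooth_sigma Kernel SD in grid steps.
#' @param overnight_window Clock-hour interval (start, end) scanned for the
#'   stable overnight baseline.
#' @param baseline_window Width of the sliding overnight window, minutes.
#' @param baseline_step Step of the sliding overnight window, minutes.
#' @param drift_window Width of the sliding window used to anchor the
#'   slow-drift baseline, minutes.
#' @param drift_step Spacing of drift-baseline anchor points, minutes.
#' @param drift_quantile Quantile tracked within each drift window; a low
#'   quantile follows the fasting envelope without chasing meal peaks.
#' @param min_drift_duration Segments shorter than this (minutes) skip drift
#'   correction (insufficient support) and are flagged.
#' @param lag_window Interval after each EMA, minutes, whose gridded CGM
#'   samples are averaged into the matched glucose value (closed interval).
#' @param min_runs Minimum number of EMA runs with concurrent CGM required to
#'   include a participant.
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(max_gap = 20,
                              grid_step = 5,
                              smooth_window = 5,
                              smooth_sigma = 1,
                              overnight_window = c(0, 8),
                              baseline_window = 60,
                              baseline_step = 5,
                              drift_window = 240,
                              drift_step = 60,
                              drift_quantile = 0.10,
                              min_drift_duration = 120,
                              lag_window = c(5, 10),
                              min_runs = 20) {
  stopifnot(
    max_gap > grid_step,
    grid_step > 0,
    smooth_window %% 2 == 1,
    smooth_sigma > 0,
    length(overnight_window) == 2,
    overnight_window[1] < overnight_window[2],
    baseline_window > 0, baseline_step > 0,
    drift_window > 0, drift_step > 0,
    drift_quantile > 0, drift_quantile < 1,
    length(lag_window) == 2,
    lag_window[1] < lag_window[2],
    min_runs >= 0
  )
  cfg <- as.list(environment())
  class(cfg) <- "preprocess_config"
  cfg
}

# deterministic sub-seed derivation; keeps every derived seed < 2^31
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
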