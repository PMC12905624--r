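#' Summarise the proportion mediated from per-draw effects
#'
#' The proportion mediated is the per-draw ratio of the indirect effect to the
#' total effect. Ratio draws whose denominator is within a machine-scaled
#' epsilon of zero are excluded and counted rather than sign-fixed; when the
#' total effect's interval covers zero the ratio distribution is heavy-tailed
#' and the summary is flagged as unstable (a wide interval is expected, not an
#' error).
#'
#' @param acme_draws,total_draws Per-draw indirect and total effects.
#' @param conf Confidence level.
#' @return List: `estimate` (median of retained ratio draws), `ci`,
#'   `n_excluded`, `unstable` (logical), `draws` (retained ratios).
#' @export
proportion_mediated <- function(acme_draws, total_draws, conf = 0.95) {
  stopifnot(length(acme_draws) == length(total_draws), length(acme_draws) > 0)
  eps <- sqrt(.Machine$double.eps) * max(1, max(abs(total_draws)))
  keep <- abs(total_draws) > eps
  if (!any(keep)) stop("all total-effect draws are numerically zero")
  ratios <- acme_draws[keep] / total_draws[keep]
  alpha <- 1 - conf
  total_ci <- quantile(total_draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(
    estimate = median(ratios),
    ci = quantile(ratios, c(alpha / 2, 1 - alpha / 2), names = FALSE),
    n_excluded = sum(!keep),
    unstable = total_ci[1] <= 0 && total_ci[2] >= 0,
    draws = ratios
  )
}

draw_p_value <- function(draws) {
  2 * min(mean(draws <= 0), mean(draws >= 0))
}

#' Quasi-Bayesian multilevel mediation
#'
#' Decomposes the glucose -> mood association into its indirect path via the
#' perceived metabolic state and the direct path, by Monte-Carlo propagation
#' of fixed-effect uncertainty. `n_sims` parameter vectors are drawn from each
#' fitted model's asymptotic sampling distribution (multivariate normal over
#' the fixed effects with the estimated covariance; random-effect uncertainty
#' enters through that covariance). Per draw, with `a` the mediator-model
#' treatment slope, `b` the outcome-model mediator slope and `c'` the
#' outcome-model treatment slope: ACME = a*b, ADE = c', total = ACME + ADE
#' (exact per draw, since the models are linear with no treatment-mediator
#' interaction), proportion mediated = ACME / total. Point estimates are
#' per-quantity medians of the draws, intervals are percentile intervals, and
#' p-values are twice the smaller tail share of draws beyond zero.
#'
#' @param mediator_fit `glyco_fit` of the mediator model (metabolic state on
#'   glucose).
#' @param outcome_fit `glyco_fit` of the outcome model (mood on glucose and
#'   metabolic state).
#' @param treatment Treatment term name, present in both models.
#' @param mediator Mediator term name in the outcome model.
#' @param n_sims Number of parameter draws (>= 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List of class `glyco_mediation`: `acme`, `ade`, `total`,
#'   `prop_mediated` (each with `estimate`, `ci`, `p` where defined),
#'   `draws` (per-draw arrays), `n_sims`, `prop_unstable`, `prop_excluded`.
#' @export
quasi_bayesian_mediate <- function(mediator_fit, outcome_fit,
                                   treatment = "z_ln_glucose",
                                   mediator = "z_metabolic_state",
                                   n_sims = 10000, seed = 1L, conf = 0.95) {
  stopifnot(n_sims >= 1000)
  med_coef <- mediator_fit$coefficients
  out_coef <- outcome_fit$coefficients
  if (!treatment %in% med_coef$term)
    stop("treatment '", treatment, "' not in mediator model")
  if (!all(c(treatment, mediator) %in% out_coef$term))
    stop("treatment and mediator must both appear in the outcome model")
  v_med <- mediator_fit$vcov_fixed
  v_out <- outcome_fit$vcov_fixed
  if (is.null(v_med) || is.null(v_out))
    stop("fixed-effect covariance missing from a model fit")

  set.seed(seed)
  draws_med <- MASS::mvrnorm(n_sims, mu = med_coef$estimate, Sigma = v_med)
  draws_out <- MASS::mvrnorm(n_sims, mu = out_coef$estimate, Sigma = v_out)
  a <- draws_med[, match(treatment, med_coef$term)]
  b <- draws_out[, match(mediator, out_coef$term)]
  c_prime <- draws_out[, match(treatment, out_coef$term)]

  acme <- a * b
  ade <- c_prime
  total <- acme + ade
  alpha <- 1 - conf
  summarise <- function(x) list(
    estimate = median(x),
    ci = quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE),
    p = draw_p_value(x)
  )
  prop <- proportion_mediated(acme, total, conf = conf)
  structure(list(
    acme = summarise(acme),
    ade = summarise(ade),
    total = summarise(total),
    prop_mediated = list(estimate = prop$estimate, ci = prop$ci,
                         p = draw_p_value(prop$draws)),
    prop_unstable = prop$unstable,
    prop_excluded = prop$n_excluded,
    draws = list(a = a, b = b, c_prime = c_prime, acme = acme, ade = ade,
                 total = total),
    n_sims = n_sims,
    treatment = treatment,
    mediator = mediator
  ), class = "glyco_mediation")
}

#' @export
print.glyco_mediation <- function(x, ...) {
  row <- function(nm, s) cat(sprintf(
    "  %-18s %8.3f  95%% CI [%7.3f, %7.3f]  p = %.4g\n",
    nm, s$estimate, s$ci[1], s$ci[2], s$p))
  cat("Quasi-Bayesian mediation (", x$n_sims, " draws)\n", sep = "")
  row("ACME (indirect)", x$acme)
  row("ADE (direct)", x$ade)
  row("total effect", x$total)
  row("prop. mediated", x$prop_mediated)
  if (x$prop_unstable)
    cat("  note: total-effect CI covers 0; proportion mediated is unstable\n")
  invisible(x)
}

#' Fit the mediation model pair and decompose the glucose-mood effect
#'
#' Convenience wrapper: fits the mediator model (standardised metabolic state
#' on standardised ln-glucose, random intercept and glucose slope) and the
#' outcome model (mood on glucose and metabolic state, random intercept and
#' both slopes, no treatment-mediator interaction), then runs
#' [quasi_bayesian_mediate()]. A separate total-effect model (mood on glucose
#' alone) is also fitted for comparison with the combined-model total.
#'
#' @param aligned Aligned observation table.
#' @param n_sims,seed,conf Passed to [quasi_bayesian_mediate()].
#' @return `glyco_mediation` with additional elements `mediator_fit`,
#'   `outcome_fit`, `total_effect_model` (marginal glucose slope from the
#'   separate model).
#' @export
mediate_glucose_mood <- function(aligned, n_sims = 10000, seed = 1L,
                                 conf = 0.95) {
  med_fit <- fit_lme(
    lme_spec("z_metabolic_state", "z_ln_glucose", "z_ln_glucose",
             label = "mediator model"), aligned)
  out_fit <- fit_lme(
    lme_spec("mood_state", "z_ln_glucose + z_metabolic_state",
             c("z_ln_glucose", "z_metabolic_state"),
             label = "outcome model"), aligned)
  res <- quasi_bayesian_mediate(med_fit, out_fit, n_sims = n_sims, seed = seed,
                                conf = conf)
  marg <- fit_lme(
    lme_spec("mood_state", "z_ln_glucose", "z_ln_glucose",
             label = "total-effect model"), aligned)
  res$mediator_fit <- med_fit
  res$outcome_fit <- out_fit
  res$total_effect_model <- marg$coefficients[
    marg$coefficients$term == "z_ln_glucose", , drop = FALSE]
  res
}
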