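#' Specify a linear mixed-effects model
#'
#' @param outcome Outcome column name.
#' @param fixed Character string of fixed-effect terms (right-hand side,
#'   e.g. `"z_ln_glucose * z_metabolic_state"`).
#' @param slopes Character vector of random-slope terms per participant; every
#'   slope must also appear among the fixed effects.
#' @param group Grouping column (participant identifier).
#' @param reml Restricted maximum likelihood (default) or full ML.
#' @param label Identifier used in messages.
#' @return List of class `lme_spec`.
#' @export
lme_spec <- function(outcome, fixed, slopes = character(0),
                     group = "participant_id", reml = TRUE, label = outcome) {
  fixed_vars <- all.vars(as.formula(paste("~", fixed)))
  if (!all(slopes %in% fixed_vars))
    stop("every random slope must also appear as a fixed effect: ",
         paste(setdiff(slopes, fixed_vars), collapse = ", "))
  structure(list(outcome = outcome, fixed = fixed, slopes = slopes,
                 group = group, reml = reml, label = label),
            class = "lme_spec")
}

build_formula <- function(spec, re = c("correlated", "uncorrelated", "intercept")) {
  re <- match.arg(re)
  re_part <- switch(re,
    correlated = paste0("(1 + ", paste(spec$slopes, collapse = " + "),
                        " | ", spec$group, ")"),
    uncorrelated = paste0("(1 + ", paste(spec$slopes, collapse = " + "),
                          " || ", spec$group, ")"),
    intercept = paste0("(1 | ", spec$group, ")")
  )
  if (length(spec$slopes) == 0) re_part <- paste0("(1 | ", spec$group, ")")
  as.formula(paste(spec$outcome, "~", spec$fixed, "+", re_part))
}

# conditional modes per group; uncorrelated (`||`) fits return one block per
# random term under the same factor name, merged here into one data frame
merge_ranef <- function(fit, group) {
  re <- lme4::ranef(fit)
  blocks <- re[names(re) == group]
  out <- blocks[[1]]
  if (length(blocks) > 1) {
    for (b in blocks[-1]) {
      b <- b[rownames(out), , drop = FALSE]
      for (cn in colnames(b)) out[[cn]] <- b[[cn]]
    }
  }
  out
}

fit_once <- function(formula, data, reml) {
  warnings <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(formula, data = data, REML = reml),
      error = function(e) e
    ),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  failed <- inherits(fit, "error") ||
    any(grepl("failed to converge|unable to evaluate|Hessian", warnings,
              ignore.case = TRUE))
  list(fit = fit, failed = failed, warnings = warnings)
}

#' Fit a mixed model with a conservative fallback ladder
#'
#' Fits the specified model with correlated random effects. On convergence
#' failure it refits with uncorrelated random effects, then with a random
#' intercept only, flagging each fallback; the fixed-effect specification is
#' never changed. A singular (boundary) fit — a random-effect variance
#' estimated at zero — is retained and flagged, not refitted. Degrees of
#' freedom use the Satterthwaite approximation; confidence intervals are
#' Wald-t at those df.
#'
#' @param spec An [lme_spec()].
#' @param data Aligned observation table.
#' @param conf Confidence level.
#' @return List of class `glyco_fit`: `coefficients` (term, estimate, se, df,
#'   t, p, ci_lo, ci_hi), `vcov_fixed`, `ranef` (conditional modes), `model`,
#'   `fallback`, `singular`, `spec`.
#' @export
fit_lme <- function(spec, data, conf = 0.95) {
  if (length(unique(data[[spec$group]])) < 2)
    stop("model '", spec$label, "': need at least 2 participants ",
         "(no between-person variance with one group)")
  vars <- unique(c(spec$outcome, all.vars(as.formula(paste("~", spec$fixed))),
                   spec$group))
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]

  ladder <- if (length(spec$slopes) > 0)
    c("correlated", "uncorrelated", "intercept") else "intercept"
  fallback <- "none"
  res <- NULL
  for (level in ladder) {
    res <- fit_once(build_formula(spec, level), data, spec$reml)
    if (!res$failed) {
      fallback <- if (level == ladder[1]) "none" else level
      break
    }
  }
  if (is.null(res) || inherits(res$fit, "error") || res$failed)
    stop("model '", spec$label, "': singular/non-convergent after all ",
         "fallbacks: ", paste(res$warnings, collapse = "; "))

  fit <- res$fit
  sm <- summary(fit)$coefficients
  alpha <- 1 - conf
  crit <- qt(1 - alpha / 2, sm[, "df"])
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    df = sm[, "df"],
    t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    ci_lo = sm[, "Estimate"] - crit * sm[, "Std. Error"],
    ci_hi = sm[, "Estimate"] + crit * sm[, "Std. Error"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    vcov_fixed = as.matrix(vcov(fit)),
    ranef = merge_ranef(fit, spec$group),
    model = fit,
    fallback = fallback,
    singular = lme4::isSingular(fit),
    n_obs = nrow(data),
    n_groups = length(unique(data[[spec$group]])),
    spec = spec
  ), class = "glyco_fit")
}

#' @export
print.glyco_fit <- function(x, ...) {
  cat("Mixed model:", x$spec$label,
      sprintf("(n = %d obs, %d participants)\n", x$n_obs, x$n_groups))
  if (x$fallback != "none") cat("  fallback:", x$fallback, "\n")
  if (x$singular) cat("  note: singular fit (a variance component is zero)\n")
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Catalogue of the study's mixed-effects models
#'
#' Base models regress each outcome on standardised ln-glucose (or metabolic
#' state) with random intercepts and the corresponding random slopes per
#' participant. Extended models add standardised BMI, age, sex and the
#' residualised HOMA-IR together with their interactions with the
#' within-person predictors.
#'
#' @param extended Include the covariate/interaction terms.
#' @return Named list of [lme_spec()] objects: `mood_glucose`,
#'   `hunger_glucose`, `satiety_glucose`, `metabolic_glucose`,
#'   `mood_metabolic`, `mood_glucose_metabolic`.
#' @export
model_catalogue <- function(extended = FALSE) {
  cov_terms <- "(z_bmi + z_age + sex + z_homa_res)"
  g <- if (extended) paste0("z_ln_glucose * ", cov_terms) else "z_ln_glucose"
  m <- if (extended) paste0("z_metabolic_state * ", cov_terms) else "z_metabolic_state"
  gm <- if (extended)
    paste0("z_ln_glucose * z_metabolic_state + (z_ln_glucose + z_metabolic_state) * ",
           cov_terms)
  else "z_ln_glucose * z_metabolic_state"
  list(
    mood_glucose = lme_spec("mood_state", g, "z_ln_glucose",
                            label = "mood ~ glucose"),
    hunger_glucose = lme_spec("hunger", g, "z_ln_glucose",
                              label = "hunger ~ glucose"),
    satiety_glucose = lme_spec("satiety", g, "z_ln_glucose",
                               label = "satiety ~ glucose"),
    metabolic_glucose = lme_spec("metabolic_state", g, "z_ln_glucose",
                                 label = "metabolic state ~ glucose"),
    mood_metabolic = lme_spec("mood_state", m, "z_metabolic_state",
                              label = "mood ~ metabolic state"),
    mood_glucose_metabolic = lme_spec(
      "mood_state", gm, c("z_ln_glucose", "z_metabolic_state"),
      label = "mood ~ glucose x metabolic state")
  )
}

#' Fit the full set of study models
#'
#' @param aligned Aligned observation table (see [build_aligned()]).
#' @param extended Use the covariate-extended specifications.
#' @return Named list of `glyco_fit` objects.
#' @export
fit_study_models <- function(aligned, extended = FALSE) {
  lapply(model_catalogue(extended = extended), fit_lme, data = aligned)
}

#' Per-participant interoceptive accuracy
#'
#' Fits the glucose -> metabolic-state mixed model with a random intercept and
#' random glucose slope, forms each participant's slope as fixed effect plus
#' conditional mode (shrunken towards the population slope, not a separate
#' per-person regression), and inverts it so that stronger negative
#' glucose-hunger coupling maps to higher accuracy. The reverse regression
#' (glucose predicted from metabolic state) is available behind
#' `direction = "metabolic_to_glucose"`.
#'
#' @param aligned Aligned observation table.
#' @param direction Which variable predicts which.
#' @return Data frame: `participant_id`, `slope` (per-participant), `accuracy`
#'   (= -slope), with the underlying fit in attribute `"fit"`.
#' @export
interoceptive_accuracy <- function(aligned,
                                   direction = c("glucose_to_metabolic",
                                                 "metabolic_to_glucose")) {
  direction <- match.arg(direction)
  spec <- if (direction == "glucose_to_metabolic") {
    lme_spec("z_metabolic_state", "z_ln_glucose", "z_ln_glucose",
             label = "interoceptive accuracy")
  } else {
    lme_spec("z_ln_glucose", "z_metabolic_state", "z_metabolic_state",
             label = "interoceptive accuracy (reversed)")
  }
  fit <- fit_lme(spec, aligned)
  slope_term <- spec$slopes
  fixed_slope <- fit$coefficients$estimate[fit$coefficients$term == slope_term]
  re <- fit$ranef
  re_slope <- if (!is.null(re) && slope_term %in% colnames(re))
    re[[slope_term]] else rep(0, nrow(re))
  out <- data.frame(
    participant_id = rownames(re),
    slope = fixed_slope + re_slope,
    stringsAsFactors = FALSE
  )
  out$accuracy <- -out$slope
  attr(out, "fit") <- fit
  out
}

#' Per-participant mood level and fluctuation
#'
#' @param aligned Aligned observation table with `mood_state`.
#' @return Data frame: `participant_id`, `mood_mean`, `mood_sd` (sample SD,
#'   NA with fewer than 2 observations), `n_obs`.
#' @export
mood_summary <- function(aligned) {
  sp <- split(aligned$mood_state, aligned$participant_id)
  data.frame(
    participant_id = names(sp),
    mood_mean = vapply(sp, mean, 0),
    mood_sd = vapply(sp, function(x) if (length(x) >= 2) sd(x) else NA_real_, 0),
    n_obs = vapply(sp, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Participant-level models of mood by interoceptive accuracy
#'
#' Ordinary linear models of average mood and mood fluctuation (within-person
#' SD) on interoceptive accuracy with BMI, age and sex as covariates and their
#' interactions with accuracy; plus a model of accuracy itself on BMI,
#' residualised HOMA-IR, sex (with their interactions) and age. Accuracy, BMI
#' and age are z-standardised across participants so main effects are
#' evaluated at covariate means.
#'
#' @param scores Output of [interoceptive_accuracy()].
#' @param moods Output of [mood_summary()].
#' @param participants Participant table (with derived indices for the
#'   accuracy model).
#' @return List of `lm` fits: `mood_mean`, `mood_sd`, and (when
#'   `homa_ir_residual` is available) `accuracy`.
#' @export
accuracy_models <- function(scores, moods, participants) {
  d <- merge(merge(scores, moods, by = "participant_id"),
             participants, by = "participant_id")
  d$z_accuracy <- z_standardise(d$accuracy)
  d$z_bmi <- z_standardise(d$bmi)
  d$z_age <- z_standardise(d$age)
  d$sex <- factor(d$sex)
  check_df <- function(formula) {
    X <- stats::model.matrix(formula, d)
    if (nrow(X) <= ncol(X))
      stop("fewer participants than parameters in participant-level model")
  }
  f_mean <- mood_mean ~ z_accuracy * (z_bmi + z_age + sex)
  f_sd <- mood_sd ~ z_accuracy * (z_bmi + z_age + sex)
  check_df(f_mean)
  out <- list(
    mood_mean = lm(f_mean, data = d),
    mood_sd = lm(f_sd, data = d)
  )
  if ("homa_ir_residual" %in% names(d)) {
    d$z_homa_res <- z_standardise(d$homa_ir_residual)
    out$accuracy <- lm(z_accuracy ~ z_bmi * z_homa_res * sex + z_age, data = d)
  }
  attr(out, "data") <- d
  out
}

# recompute observation-level z-scores from raw columns (used after
# subsetting, so every fitted dataset has grand mean 0 / SD 1 predictors)
restandardise_aligned <- function(aligned, participants) {
  aligned$z_ln_glucose <- z_standardise(aligned$ln_glucose)
  aligned$z_metabolic_state <- z_standardise(aligned$metabolic_state)
  idx <- match(aligned$participant_id, participants$participant_id)
  aligned$z_bmi <- z_standardise(participants$bmi[idx])
  aligned$z_age <- z_standardise(participants$age[idx])
  if ("homa_ir_residual" %in% names(participants))
    aligned$z_homa_res <- z_standardise(participants$homa_ir_residual[idx])
  aligned
}

#' Sensitivity refit after excluding metabolically atypical participants
#'
#' Reruns the base model set and the mediation on the subsample remaining
#' after excluding participants with obesity (BMI >= `bmi_threshold`) or with
#' elevated insulin resistance (HOMA-IR >= `homa_threshold`). Predictors are
#' re-standardised within the subsample before fitting. Reports estimate
#' deltas versus the full sample.
#'
#' @param aligned Aligned observation table.
#' @param participants Participant table with derived indices.
#' @param exclusion `"bmi"` or `"homa"`.
#' @param bmi_threshold,homa_threshold Exclusion cut-offs.
#' @param n_sims Mediation resamples.
#' @param seed Mediation seed.
#' @param min_remaining Minimum subsample size.
#' @return List: `excluded_ids`, `n_subset`, `fits` (subset), `full_fits`,
#'   `deltas` (subset minus full fixed-effect estimates), `mediation`.
#' @export
sensitivity_refit <- function(aligned, participants,
                              exclusion = c("bmi", "homa"),
                              bmi_threshold = 30, homa_threshold = 2.5,
                              n_sims = 1000, seed = 1L, min_remaining = 10) {
  exclusion <- match.arg(exclusion)
  drop_ids <- if (exclusion == "bmi") {
    participants$participant_id[participants$bmi >= bmi_threshold]
  } else {
    participants$participant_id[!is.na(participants$homa_ir_median) &
                                  participants$homa_ir_median >= homa_threshold]
  }
  keep <- !(aligned$participant_id %in% drop_ids)
  n_subset <- length(unique(aligned$participant_id[keep]))
  if (n_subset < min_remaining)
    stop("exclusion leaves only ", n_subset, " participants (minimum ",
         min_remaining, ")")
  sub <- if (length(drop_ids) == 0) aligned else
    restandardise_aligned(aligned[keep, , drop = FALSE], participants)

  full_fits <- fit_study_models(aligned)
  sub_fits <- fit_study_models(sub)
  deltas <- lapply(names(full_fits), function(nm) {
    f <- full_fits[[nm]]$coefficients
    s <- sub_fits[[nm]]$coefficients
    common <- intersect(f$term, s$term)
    data.frame(model = nm, term = common,
               full = f$estimate[match(common, f$term)],
               subset = s$estimate[match(common, s$term)],
               delta = s$estimate[match(common, s$term)] -
                 f$estimate[match(common, f$term)],
               full_se = f$se[match(common, f$term)],
               stringsAsFactors = FALSE)
  })
  med <- mediate_glucose_mood(sub, n_sims = n_sims, seed = seed)
  list(excluded_ids = drop_ids, n_subset = n_subset,
       fits = sub_fits, full_fits = full_fits,
       deltas = do.call(rbind, deltas), mediation = med)
}
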