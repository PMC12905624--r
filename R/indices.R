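#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `glucose * insulin / 405` with fasting glucose in mg/dL and fasting insulin
#' in mU/L. Higher values reflect lower insulin sensitivity.
#'
#' @param glucose Fasting glucose, mg/dL.
#' @param insulin Fasting insulin, mU/L.
#' @return HOMA-IR (unitless), elementwise.
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0 | insulin <= 0, na.rm = TRUE))
    stop("glucose and insulin must be positive")
  glucose * insulin / 405
}

#' Triglyceride-glucose (TyG) index
#'
#' Surrogate insulin-resistance marker from fasting lipids and glucose. The
#' classic form is `ln(TG * G / 2)`; a halved variant `ln(TG * G / 2) / 2` is
#' also in circulation and selectable, since published cohort values near 4.4
#' sit on that scale. Neither variant is asserted as the only correct one.
#'
#' @param triglycerides Fasting triglycerides, mg/dL.
#' @param glucose Fasting glucose, mg/dL.
#' @param variant `"classic"` or `"halved"`.
#' @return TyG index, elementwise.
#' @export
tyg <- function(triglycerides, glucose, variant = c("classic", "halved")) {
  variant <- match.arg(variant)
  if (any(triglycerides <= 0 | glucose <= 0, na.rm = TRUE))
    stop("triglycerides and glucose must be positive")
  v <- log(triglycerides * glucose / 2)
  if (variant == "halved") v / 2 else v
}

#' Residualise an index against demographic covariates
#'
#' Ordinary least-squares residuals of `values` on BMI + sex + age across
#' participants, isolating the part of (ln-transformed) insulin resistance not
#' explained by body composition, sex or age. Residualising is a projection:
#' applying it twice equals applying it once, and residuals are orthogonal to
#' every covariate in-sample.
#'
#' @param values Numeric vector (typically ln HOMA-IR), one per participant.
#' @param covariates Data frame with columns `bmi`, `sex`, `age`.
#' @return Residual vector (same order; NA where inputs are missing).
#' @export
residualise <- function(values, covariates) {
  stopifnot(all(c("bmi", "sex", "age") %in% names(covariates)))
  d <- data.frame(y = values, bmi = covariates$bmi,
                  sex = factor(covariates$sex), age = covariates$age)
  X <- stats::model.matrix(~ bmi + sex + age, d)
  kappa_x <- kappa(X, exact = TRUE)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates in residualisation (condition number ",
         format(kappa_x, digits = 4), ")")
  fit <- lm(y ~ bmi + sex + age, data = d, na.action = stats::na.exclude)
  as.numeric(resid(fit))
}

#' Derive participant-level metabolic indices
#'
#' Per participant: HOMA-IR per fasting draw summarised by the median over
#' available draws, its natural log, the TyG index (median over draws, both
#' variants), the elevated-HOMA-IR flag (>= 2.5), and the ln-HOMA-IR residual
#' adjusted for BMI, sex and age.
#'
#' @param participants Participant table with `fasting_glucose_1..3`,
#'   `fasting_insulin_1..3`, `triglycerides_1..3`, `bmi`, `sex`, `age`.
#' @param tyg_variant Passed to [tyg()].
#' @return `participants` with `homa_ir_median`, `ln_homa_ir`,
#'   `homa_ir_residual`, `tyg_median`, `elevated_homa` appended.
#' @export
derive_indices <- function(participants, tyg_variant = "classic") {
  g <- as.matrix(participants[, paste0("fasting_glucose_", 1:3)])
  i <- as.matrix(participants[, paste0("fasting_insulin_", 1:3)])
  tg <- as.matrix(participants[, paste0("triglycerides_", 1:3)])
  homa_draws <- ifelse(is.na(g) | is.na(i), NA_real_, g * i / 405)
  participants$homa_ir_median <- apply(homa_draws, 1, function(x)
    if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  participants$ln_homa_ir <- log(participants$homa_ir_median)
  tyg_draws <- ifelse(is.na(g) | is.na(tg), NA_real_,
                      tyg(ifelse(is.na(tg), 1, tg), ifelse(is.na(g), 1, g),
                          variant = tyg_variant))
  participants$tyg_median <- apply(tyg_draws, 1, function(x)
    if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE))
  participants$elevated_homa <- participants$homa_ir_median >= 2.5
  participants$homa_ir_residual <- residualise(
    participants$ln_homa_ir,
    participants[, c("bmi", "sex", "age")]
  )
  participants
}
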