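#' Bipolar composite affect and metabolic scores
#'
#' Mood state = happy - sad (range -100 positive-negative) and metabolic
#' state = hunger - satiety (positive = hungry). A missing component yields a
#' missing composite.
#'
#' @param records Data frame with VAS columns `happy`, `sad`, `hunger`,
#'   `satiety`, each in \[0, 100\].
#' @return The input with `mood_state` and `metabolic_state` added.
#' @export
compute_composites <- function(records) {
  for (col in c("happy", "sad", "hunger", "satiety")) {
    x <- records[[col]]
    if (any(x < 0 | x > 100, na.rm = TRUE))
      stop("VAS rating outside [0, 100] in column '", col, "'")
  }
  records$mood_state <- records$happy - records$sad
  records$metabolic_state <- records$hunger - records$satiety
  records
}

#' Natural-log transform of glucose values
#'
#' Glucose distributions are right-skewed; parametric models use ln-glucose.
#'
#' @param values Glucose, mg/dL (> 0).
#' @return `log(values)`.
#' @export
transform_glucose <- function(values) {
  if (any(values <= 0, na.rm = TRUE))
    stop("glucose values must be positive for the log transform")
  log(values)
}

#' z-standardise across all observations
#'
#' Grand-mean centring and scaling by the sample (n-1) SD, pooled over all
#' rows — not within person — so fixed-effect slopes are comparable across
#' predictors.
#'
#' @param values Numeric vector (NA allowed, >= 2 distinct non-missing values).
#' @return Standardised vector with mean 0 and SD 1 over non-missing entries.
#' @export
z_standardise <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to standardise")
  s <- sd(values[ok])
  if (s == 0) stop("cannot z-standardise a zero-variance vector")
  (values - mean(values[ok])) / s
}

#' Build the aligned modelling table
#'
#' Joins composites, the matched glucose value and participant-level
#' covariates, applies participant QC (minimum concurrent runs), and computes
#' the observation-level standardised predictors after QC: `z_ln_glucose` and
#' `z_metabolic_state`. Participant covariates (`z_bmi`, `z_age`,
#' `z_homa_res`) are standardised across observations too, mirroring how the
#' models treat all predictors as continuous on a common scale.
#'
#' @param ema EMA records with matched `glucose` (see
#'   [align_glucose_to_ema()]).
#' @param participants Participant table; if it carries `homa_ir_residual`
#'   (see [derive_indices()]) that column is standardised into `z_homa_res`.
#' @param config A [preprocess_config()] (for the QC threshold).
#' @return List with `aligned` (modelling rows: QC-included participants,
#'   observations with concurrent glucose) and `qc` (per-participant counts
#'   and inclusion flags).
#' @export
build_aligned <- function(ema, participants, config = preprocess_config()) {
  ema <- compute_composites(ema)
  counts <- tapply(!is.na(ema$glucose), ema$participant_id, sum)
  qc <- data.frame(
    participant_id = names(counts),
    n_concurrent = as.integer(counts),
    include = as.integer(counts) >= config$min_runs,
    stringsAsFactors = FALSE
  )
  keep_ids <- qc$participant_id[qc$include]
  aligned <- ema[ema$participant_id %in% keep_ids & !is.na(ema$glucose), ,
                 drop = FALSE]
  aligned$ln_glucose <- transform_glucose(aligned$glucose)
  aligned$z_ln_glucose <- z_standardise(aligned$ln_glucose)
  aligned$z_metabolic_state <- z_standardise(aligned$metabolic_state)

  idx <- match(aligned$participant_id, participants$participant_id)
  aligned$sex <- factor(participants$sex[idx])
  aligned$z_bmi <- z_standardise(participants$bmi[idx])
  aligned$z_age <- z_standardise(participants$age[idx])
  if ("homa_ir_residual" %in% names(participants))
    aligned$z_homa_res <- z_standardise(participants$homa_ir_residual[idx])
  rownames(aligned) <- NULL
  list(aligned = aligned, qc = qc)
}

#' Aligned modelling table straight from generator ground truth
#'
#' Builds the modelling table for a simulated cohort using the clean glucose
#' value at each assessment time as the matched glucose, bypassing the CGM
#' conditioning chain. This isolates the estimators (mixed models, accuracy
#' extraction, mediation) from sensor-noise recovery, which has its own
#' checks; simulation studies of the estimators run on this table.
#'
#' @param cohort A `glyco_cohort` from [simulate_cohort()].
#' @param config A [preprocess_config()] (QC threshold).
#' @return The `aligned` data frame (see [build_aligned()]).
#' @export
aligned_from_truth <- function(cohort, config = preprocess_config()) {
  ema <- cohort$truth$ema
  ema$glucose <- ema$glucose_clean
  participants <- derive_indices(cohort$participants)
  build_aligned(ema, participants, config)$aligned
}
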