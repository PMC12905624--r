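#!/usr/bin/env Rscript
# Condition the CGM signal (segmentation, interpolation, drift removal,
# stable-baseline re-referencing, smoothing, 5-min gridding), match each EMA
# to the glucose recorded 5-10 min after it, apply participant QC, and build
# the aligned modelling table with standardised predictors.

library(glycomood)

cgm <- read_cgm_csv("results/data/cgm.csv")
ema <- read_ema_csv("results/data/ema.csv")
participants <- read_participants_csv("results/data/participants.csv")

config <- preprocess_config()
pre <- suppressWarnings(preprocess_cgm(cgm, config, verbose = TRUE))
ema_matched <- align_glucose_to_ema(pre$gridded, ema, config)
participants <- derive_indices(participants)
built <- build_aligned(ema_matched, participants, config)

cat(sprintf(
  "\nIncluded %d / %d participants (>= %d concurrent runs); %d aligned observations\n",
  sum(built$qc$include), nrow(built$qc), config$min_runs, nrow(built$aligned)))
cat(sprintf("Concurrent runs per participant: mean %.1f, range %d-%d\n",
            mean(built$qc$n_concurrent), min(built$qc$n_concurrent),
            max(built$qc$n_concurrent)))
cat(sprintf("Fasting indices: HOMA-IR median %.2f (elevated >= 2.5: %d), TyG %.2f\n",
            median(participants$homa_ir_median, na.rm = TRUE),
            sum(participants$elevated_homa, na.rm = TRUE),
            median(participants$tyg_median, na.rm = TRUE)))

dir.create("results", showWarnings = FALSE)
al <- built$aligned
al$timestamp <- format(al$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
write.csv(al, "results/aligned.csv", row.names = FALSE)
write.csv(participants, "results/participants_derived.csv", row.names = FALSE)
write.csv(pre$log, "results/preprocess_log.csv", row.names = FALSE)
write.csv(built$qc, "results/qc.csv", row.names = FALSE)
cat("Wrote results/aligned.csv, participants_derived.csv, preprocess_log.csv, qc.csv\n")
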