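#!/usr/bin/env Rscript
# Fit the mixed-effects models: mood on glucose; hunger/satiety/metabolic
# state on glucose; mood on metabolic state; mood on glucose x metabolic
# state — base and covariate-extended variants — and the participant-level
# interoceptive-accuracy analyses.

library(glycomood)

aligned <- read.csv("results/aligned.csv", stringsAsFactors = FALSE)
aligned$sex <- factor(aligned$sex)
participants <- read.csv("results/participants_derived.csv",
                         stringsAsFactors = FALSE)

fits <- fit_study_models(aligned)
fits_ext <- fit_study_models(aligned, extended = TRUE)

cat("Base models (key slope, 95% CI):\n")
for (f in fits) {
  key <- f$spec$slopes[1]
  row <- f$coefficients[f$coefficients$term == key, ]
  cat(sprintf("  %-34s b = %7.3f [%7.3f, %7.3f]  p = %.3g%s\n",
              f$spec$label, row$estimate, row$ci_lo, row$ci_hi, row$p,
              if (f$fallback != "none") paste0("  (", f$fallback, ")") else ""))
}
inter <- fits$mood_glucose_metabolic$coefficients
ix <- inter[inter$term == "z_ln_glucose:z_metabolic_state", ]
cat(sprintf("  glucose x metabolic interaction    b = %7.3f [%7.3f, %7.3f]  p = %.3g\n",
            ix$estimate, ix$ci_lo, ix$ci_hi, ix$p))

scores <- interoceptive_accuracy(aligned)
moods <- mood_summary(aligned)
acc <- accuracy_models(scores, moods, participants)
cs <- function(m, term) {
  s <- summary(m)$coefficients
  sprintf("b = %7.3f, p = %.3g", s[term, 1], s[term, 4])
}
cat("\nInteroceptive accuracy (participant level):\n")
cat("  mood mean ~ accuracy:        ", cs(acc$mood_mean, "z_accuracy"), "\n")
cat("  mood SD   ~ accuracy:        ", cs(acc$mood_sd, "z_accuracy"), "\n")
cat("  accuracy  ~ BMI:             ", cs(acc$accuracy, "z_bmi"), "\n")

tab <- do.call(rbind, lapply(names(fits), function(nm)
  cbind(model = nm, fits[[nm]]$coefficients)))
tab_ext <- do.call(rbind, lapply(names(fits_ext), function(nm)
  cbind(model = paste0(nm, "_ext"), fits_ext[[nm]]$coefficients)))
write.csv(rbind(tab, tab_ext), "results/model_coefficients.csv",
          row.names = FALSE)
write.csv(merge(scores, moods, by = "participant_id"),
          "results/interoception.csv", row.names = FALSE)
cat("\nWrote results/model_coefficients.csv, results/interoception.csv\n")
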