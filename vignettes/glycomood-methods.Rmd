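---
title: "Methods: from interstitial glucose to mood, via perceived metabolic state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from interstitial glucose to mood, via perceived metabolic state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomood)
```

## The question and the estimand

Hunger is commonly linked to worse mood, but a low glucose level could act on
mood through two different routes: directly (subconscious physiological
signalling) or indirectly, through the consciously perceived metabolic state.
With four weeks of continuous glucose monitoring (CGM) and twice-daily
ecological momentary assessment (EMA) of mood (happy, sad) and metabolic
state (hunger, satiety), the two routes can be separated by a multilevel
mediation: the indirect path is glucose → perceived metabolic state → mood,
the direct path is whatever association with mood remains once the mediator
is held fixed. The package implements the full path from raw sensor exports
to that decomposition, and a synthetic cohort generator whose known
parameters make every stage testable.

## The synthetic cohort generator

The generator is a first-class, tested component: its defaults *are* the
study conditions the rest of the package is evaluated under.

**Glucose signal.** Per participant, the clean (drift- and noise-free) signal
is

    basal_i + circadian(t) + sum of meal excursions,

with `basal_i ~ N(85, 7)` mg/dL across participants (fasting glucose in
healthy adults), three daily meals at 08:00/13:00/19:00 jittered by 45 min,
bi-exponential excursions (rise tau 20 min, decay tau 60 min, peak 45 mg/dL
with 25 % amplitude CV) — the simplest shape that reproduces postprandial
dynamics — and a *non-negative* daytime circadian elevation (Gaussian bump,
peak 7 mg/dL at 15:00, width 4 h). The bump is deliberately zero overnight:
the overnight fasting trough then sits exactly at `basal_i`, which is the
quantity the preprocessing chain's stable-baseline stage is designed to
recover, so recovery has a well-defined target.

**Sensor artefacts.** Each sensor (one swap after 14 days) carries a smooth
calibration drift: a random cubic over its wear period rescaled to
`[0, drift_amplitude]` (default 8 mg/dL), plus, for the replacement sensor, a
half-normal step offset (scale 4 mg/dL). Both are modelled as *non-negative*
bias. This is a deliberate choice: the stable baseline is defined as a
minimum across nights, so only the lower envelope of the calibration error is
identifiable; with one-sided bias the envelope touches the true basal and the
baseline is recoverable, while a signed bias would make "the participant's
basal" ill-defined by exactly the magnitude of the most negative excursion.
Measurement noise is AR(1) (`sd` 1.5 mg/dL, `phi` 0.3) — the scale of a
factory-filtered consumer sensor stream, not of a raw electrode current.
Short dropouts (1–3 samples, 2/day) and long outages (1–8 h, 0.15/day) are
deleted; values are clamped to the 40–250 mg/dL reporting range.

**EMA schedule.** Two assessments per day in wake hours (08:00–23:00, a free
parameter; the source design reports daytime sampling but not the window),
drawn sequentially at least 2 h apart, thinned with missingness 0.145 so the
realised mean is ~48 of 56 scheduled assessments per participant.

**Latent ratings model.** At assessment time *t* of participant *i*, with
`z` the standardised clean glucose,

    m  = a_i * z + e_m,          e_m ~ N(0, 0.85)
    y  = c' * z + b * m + e_y,   e_y ~ N(0, s_i)

`a_i ~ N(-0.5, 0.15)` (truncated to stay negative: higher glucose, less
hunger), `b = -3`, `c' = 0` — an indirect-only design whose implied true
indirect effect is `mean(a_i) * b = 1.5` and true direct effect 0. The mood
noise `s_i = 12 + 12 * (1 - |a_i|)` couples mood fluctuation to coupling
strength, so participants whose ratings track glucose closely fluctuate less
— the effect the participant-level analyses are meant to detect. The latents
map affinely onto 0–100 visual-analogue items with small (SD 2) item noise,
hunger/satiety and happy/sad as anti-correlated pairs; the composite scores
(hunger − satiety, happy − sad) therefore recover the latents nearly
noise-free. Centres and spreads (metabolic composite −28 ± 12 between / 15
within; mood 36 ± 20) were chosen to land the composites on the scale
reported for healthy adults (metabolic state ≈ −28 ± 18, mood ≈ 36 ± 26
across observations).

Glucose entering the latent model is standardised with the cohort-level
mean/SD of the clean signal *at the drawn assessment times*, so the
generative slopes live on the same scale as slopes fitted downstream on
observation-level standardised glucose.

**What the generator does not emulate.** No physiological glucose–insulin
dynamics (no minimal-model ODEs), no food diaries, no hormone or stress
signals, no mood autocorrelation in time, no context effects on ratings, and
a one-sided, smooth calibration error rather than the messier error structure
of real sensors. Passing recovery tests therefore shows that the estimators
are correct under the assumed statistical structure — not that real CGM/EMA
data satisfy that structure.

## CGM conditioning

The chain mirrors established physiological signal correction practice, per
participant:

1. **Segmentation** wherever consecutive samples are more than 20 min apart
   (strictly) or the sensor changes — a replacement sensor is a new
   calibration regime even without a time gap.
2. **Short-gap interpolation** linearly onto the 5-min grid inside segments;
   nothing is extrapolated, so gaps > 20 min are never bridged.
3. **Drift correction** per segment: a sliding 4-h window advanced in 1-h
   steps anchors the 0.10 quantile of the window; the anchors are smoothed
   with a monotone (Fritsch–Carlson) cubic interpolant and subtracted. A low
   quantile tracks the fasting envelope without chasing meal peaks; the
   window and quantile are free parameters of the config. The output is
   centred near zero with meal excursions preserved as positive deviations.
   Segments under 2 h lack support for a windowed baseline; they have their
   own within-segment quantile subtracted instead and are flagged — a literal
   pass-through would leave them on the absolute scale and the subsequent
   re-referencing would double their level.
4. **Stable overnight baseline** from *raw* values: per night, a 1-h window
   slides over 00:00–08:00 in 5-min steps; window variability is the sample
   SD (the variability metric is otherwise unspecified, SD is the
   conventional choice); the night's candidate is the mean of its
   lowest-variability complete window and the baseline is the minimum
   candidate across nights. With no complete overnight window the baseline
   falls back to the 5th percentile of all raw values, flagged.
5. **Re-referencing**: the baseline is added to all drift-removed values,
   giving both sensors a common absolute anchor.
6. **Gaussian smoothing** with a 5-tap kernel (SD 1 grid step, truncated at
   ±2 steps, renormalised at segment edges); smoothing never crosses segment
   boundaries. Only the window length is prescribed; the SD is the package's
   choice.
7. **Gridding** to left-closed 5-min bins labelled by their left edge
   (device-local clock, timezone-naive; CGM and EMA share the device clock).

**Alignment.** Interstitial glucose trails blood glucose by ~5–6 min, so the
value concurrent with an assessment at *t* is recorded shortly after it. All
grid samples in the *closed* interval [t+5 min, t+10 min] are averaged — both
the 5- and the 10-minute grid points satisfy the physiological lag, and with
only one present that one is used. An empty window means no concurrent
glucose: the observation is dropped from modelling and from the
concurrent-run count. Participants enter the analysis with at least 20
concurrent runs.

## Composites, standardisation, fasting indices

Mood state = happy − sad; metabolic state = hunger − satiety (positive =
hungry), both in [−100, 100]. Glucose is ln-transformed (right-skew) and all
model predictors are z-standardised *across observations* (grand mean/SD,
sample-SD denominator), computed after QC inclusion and recomputed within any
sensitivity subsample. Group-centering is used only for plotting, never for
modelling.

HOMA-IR = fasting glucose (mg/dL) × fasting insulin (mU/L) / 405, summarised
per participant as the median over up to three draws; ln-HOMA-IR is
residualised on BMI + sex + age by OLS (a projection — idempotent and
orthogonal to the covariates by construction) and the residual standardised
for use as a covariate. The TyG index is provided in both circulating
variants, `ln(TG*G/2)` (default) and its halved form — published cohort
values near 4.4 sit on the halved scale, but no formula is asserted as the
original one.

## Mixed-effects models

All within-person models are linear mixed-effects fits (REML) with random
intercepts and random slopes for the within-person predictors, per
participant: mood ~ glucose; hunger/satiety/metabolic state ~ glucose;
mood ~ metabolic state; mood ~ glucose × metabolic state. Extended variants
add standardised BMI, age, sex and residualised HOMA-IR with their
interactions with the within-person predictors. Degrees of freedom use the
Satterthwaite approximation; intervals are Wald-t at those df.

**Fallback ladder.** On genuine convergence failure the model is refitted
with uncorrelated random effects, then with a random intercept only, each
fallback flagged; the fixed-effect specification never changes. A singular
(boundary) fit — a variance component estimated at zero, expected whenever
the generative random-slope variance is zero — is retained and flagged, not
refitted: the fixed effects of a boundary fit are valid, and silently
simplifying the model would change the estimand.

**Interoceptive accuracy** is the inverted per-participant slope of the
metabolic-state-on-glucose model: fixed slope plus the participant's
conditional mode (shrunken towards the population, not a separate per-person
regression — stable down to the 20-run minimum). Inversion makes stronger
negative glucose–hunger coupling read as higher accuracy. The source
description of the direction is internally inconsistent (state predicted from
glucose vs glucose predicted from state); the glucose → metabolic-state
direction is the default and the reverse is available via
`direction = "metabolic_to_glucose"`. Participant-level models then regress
mood mean and mood SD on accuracy × (BMI + age + sex), and accuracy itself on
BMI × residualised HOMA-IR × sex + age, with accuracy, BMI and age
standardised so main effects are evaluated at covariate means.

## Quasi-Bayesian mediation

The decomposition is computed from two mixed models — mediator:
z-metabolic-state ~ z-ln-glucose; outcome: mood ~ z-ln-glucose +
z-metabolic-state, both with the corresponding random slopes — by Monte-Carlo
propagation of fixed-effect uncertainty: 10,000 draws from each model's
asymptotic sampling distribution (multivariate normal over the fixed effects
with the estimated covariance; random-effect uncertainty enters through that
covariance). Per draw, ACME = a·b, ADE = c′, total = ACME + ADE — exact by
construction, since the models are linear and the outcome model carries no
treatment–mediator interaction (that interaction is estimated separately in
the model set and is compatible with zero under the generator's design).
Point estimates are medians of draws (robust under the ratio's skew),
intervals are percentile intervals, p-values twice the smaller tail share of
draws beyond zero.

The proportion mediated is the per-draw ratio ACME/total. Draws whose
denominator is within a machine-scaled epsilon of zero are excluded and
counted — exclusion-plus-flag is transparent and testable, unlike sign-fixing
— and whenever the total effect's interval covers zero the ratio summary is
flagged as unstable; a very wide interval is the expected behaviour there,
not an error. A separate total-effect model (mood ~ glucose alone) is always
reported next to the combined-model total, since a marginal and a
combined-model total need not coincide exactly.

## Verification strategy and problem sizes

Every stage is tested against an independent oracle: interpolation against
brute-force two-point lines, the baseline against an exhaustive window scan,
smoothing against the explicit kernel, residualisation against the normal
equations, ratio summaries against direct quantile computation, and the
estimators against the generator's ground truth.

The estimator simulations run on generator-emitted aligned observations (the
clean glucose value at the assessment time) rather than through the CGM
chain: signal recovery has its own oracle checks, and the estimator studies
are about the statistics, not the signal processing. Sizes, chosen for
binomial resolution at reasonable runtimes: mediation recovery over 50
cohorts at full study scale (90 participants, 28 days, 10,000 draws each);
accuracy rank-recovery at full scale with couplings spread uniformly over
[−0.9, −0.1] (a spread wide enough that rank recovery is informative);
mood-fluctuation sign recovery over 50 full-scale replicates; type-I error
over 200 and interval coverage over 100 smaller cohorts (30 participants, 14
days) — calibration is scale-free, so the smaller cohorts probe it just as
well.

One full end-to-end run (CGM chain included) at study scale backs the
estimator studies: the matched glucose correlates ≈ 0.95 with the clean
signal at the assessment time (lag window, smoothing, residual drift), which
attenuates the end-to-end indirect effect by roughly 5–10 % — visible in the
end-to-end mediation but small next to a single cohort's sampling spread.

## Known limitations

- The drift model (smooth cubic, one-sided) is kinder than real calibration
  error; the drift-correction quantile/window defaults are choices, and on
  real exports they should be inspected against the overnight envelope.
- Mediation identification assumes sequential ignorability; no sensitivity
  analysis for unmeasured mediator–outcome confounding is provided.
- The generator's indirect-only truth makes the proportion-mediated ratio
  well-behaved; on data with a near-zero total effect the ratio interval is
  expected to be extremely wide (and is flagged).
- Fixed-effects-only uncertainty propagation in the mediation matches the
  standard multilevel practice at this design's level but understates
  uncertainty if random-slope spread is of scientific interest in itself.
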