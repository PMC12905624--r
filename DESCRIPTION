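Package: glycomood
Title: Glucose, Metabolic State and Mood from Combined CGM and EMA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking continuous glucose monitoring (CGM) to
    momentary mood via perceived metabolic state. Provides a synthetic cohort
    generator with known ground truth, CGM signal conditioning (gap
    segmentation, short-gap interpolation, segment-wise drift correction,
    overnight stable-baseline re-referencing, Gaussian smoothing, 5-minute
    gridding and lag-aware alignment to ecological momentary assessments),
    composite affect and metabolic scores, fasting insulin-resistance indices
    (HOMA-IR, TyG), linear mixed-effects models with random slopes including a
    per-participant interoceptive-accuracy measure, and a quasi-Bayesian
    multilevel mediation decomposing the glucose-mood association into direct
    and indirect (via metabolic state) components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
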