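Package: thetapac
Title: Theta-Gamma Phase-Amplitude Coupling Biomarker Analysis for ALS EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying phase-amplitude cross-frequency coupling (PAC)
    as an EEG biomarker of cortical dysfunction in amyotrophic lateral
    sclerosis. Implements the Tort Kullback-Leibler modulation index and
    comodulograms over theta/alpha/beta phase and gamma amplitude bands at
    sensorimotor electrodes recoded by handedness, Welch band-power control
    analysis, repeated-measures mixed-model cohort statistics with post hoc
    contrasts and effect sizes, clinical phenotype classification from an
    ECAS/ALSFRS-r clinical table, corticospinal-tract diffusion-metric
    asymmetry analysis, and ROC-based patient/control stratification with
    multi-predictor logistic combination. Includes seeded synthetic-cohort
    generators (EEG with injectable coupling, clinical tables, DTI tables)
    so the full pipeline is testable end to end, plus Monte-Carlo study
    helpers for recovery, calibration and specificity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
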