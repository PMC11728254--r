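Package: silscore
Title: Shock Index/Lactate (SIL) Sepsis Triage Score and Diagnostic
    Accuracy Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Shock Index/Lactate (SIL) triage score and the
    NEWS, qSOFA and SOFA comparator scores from raw emergency-department
    vital signs and laboratory values, and provides the diagnostic-accuracy
    pipeline used to validate ordinal severity scores against in-hospital
    sepsis mortality: 2x2 accuracy statistics with binomial confidence
    intervals, prevalence-adjusted predictive values, empirical ROC curves
    and AUC with DeLong or bootstrap confidence intervals, paired AUC
    comparison, odds ratios and chi-square tests, stratum mortality tables,
    and bootstrap calibration curves. A seeded synthetic cohort generator
    reproduces the statistical structure of a 299-patient emergency
    department validation cohort so that every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
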