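Package: qeegr
Title: Quantitative EEG Analysis of Early Post-Resuscitation Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of early post-resuscitation
    electroencephalography (EEG) in experimental cardiac-arrest models.
    Detects bursts and burst suppression, classifies 60-second epochs as
    isoelectric, burst suppression or continuous background activity,
    derives recovery metrics (burst onset time, burst frequency time
    course, time of recovery of continuous background activity), and
    computes normalized spectral entropy of the delta/theta/alpha/beta
    band-power distribution from Welch averaged periodograms. Includes a
    synthetic two-channel EEG and cohort generator with known ground
    truth for validation, an outcome-statistics layer (neurologic deficit
    scoring, Welch t tests from raw or summary data, Fisher's exact test,
    two-way ANOVA with per-time post hoc tests, Kaplan-Meier and log-rank
    survival analysis, Spearman correlation, single-predictor logistic
    regression), EDF and CSV signal input/output, and an end-to-end
    simulation-to-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    survival,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
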