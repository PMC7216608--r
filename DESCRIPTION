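Package: squatscreen
Title: Reliability and Validity Analysis of Marker-Free Single-Leg-Squat Screening
Version: 0.1.0
Authors@R:
    person("Mikael", "Sundin", email = "mikael.sundin@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating camera-based movement screening of the
    single-leg squat (SLS). Scores frontal-plane knee trajectories with a
    net trajectory angle (the angle between the fitted knee path and the
    vertical axis, per squat phase), runs a full test-retest reliability
    analysis (variance-component ICC of absolute agreement, SEM, smallest
    detectable change, Wilcoxon signed-rank, Spearman correlation,
    Bland-Altman limits of agreement), and evaluates construct validity
    against dichotomous visual pass/fail ratings through a cut-off sweep of
    diagnostic accuracy (percent agreement, Cohen's kappa, sensitivity,
    specificity, predictive values, binary-test ROC/AUC). Includes a
    synthetic-data generator with a known variance structure so the whole
    pipeline is testable without access to recorded cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
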