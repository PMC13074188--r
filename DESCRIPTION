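Package: dtathresh
Title: Diagnostic Accuracy Meta-Analysis with Likelihood-Ratio Decision Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of diagnostic test accuracy from study-level
    2x2 tables, motivated by quantitative biomarkers read against a positivity
    cutoff (e.g. cerebrospinal-fluid heparin-binding protein for
    healthcare-associated ventriculitis and meningitis). Fits the bivariate
    logit-normal random-effects model by restricted maximum likelihood and derives
    pooled sensitivity and specificity, likelihood ratios and the diagnostic odds
    ratio with Monte-Carlo confidence intervals, heterogeneity statistics, and the
    between-study (threshold-effect) correlation. Provides summary ROC curves with
    confidence and prediction regions, subgroup fits and univariable
    metaregression with likelihood-ratio tests, Fagan post-test probability
    tables, Deeks' funnel-plot asymmetry test, and a multiple-cutoff model that
    regresses transformed accuracy on transformed cutoffs to locate the
    Youden-optimal cutoff (with cluster-bootstrap interval) and
    likelihood-ratio-based rule-in and rule-out thresholds. Includes a calibrated
    synthetic study-level data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
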