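Package: teenstopbang
Title: Pediatric STOP-Bang Risk Stratification for Obstructive Sleep Apnea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring engine and diagnostic-accuracy toolkit for an
    adolescent modification of the STOP-Bang obstructive sleep apnea (OSA)
    screening instrument. Collapses six-level ordinal questionnaire
    responses, derives anthropometric flags from pluggable pediatric growth
    references (LMS body-mass-index percentiles, height-age polynomial
    blood-pressure percentiles, neck-circumference 95th-percentile lookup),
    and evaluates the resulting 0-8 count score against polysomnographic
    OSA labels: 2x2 contingency tables with sensitivity, specificity,
    predictive values, likelihood ratios and prevalence-adjusted
    (post-test-odds) likelihood ratios with Wilson or Clopper-Pearson
    confidence intervals; empirical ROC curves with DeLong AUC variance,
    paired and unpaired AUC comparisons; Wilcoxon signed-rank,
    Mann-Whitney U and one-sample Kolmogorov-Smirnov tests; and a seeded
    synthetic-cohort generator with binomial-tail calibration of item
    operating characteristics for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
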