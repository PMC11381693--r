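Package: sarcomb
Title: Mining Long-Term Condition Combinations Associated with Sarcopenia Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies combinations of long-term conditions associated with
    risk of sarcopenia in multimorbid cohorts. Implements cost-sensitive
    classification trees on binary condition indicators (Gini impurity with a
    false-negative loss penalty derived from the outcome proportions), a
    bagged ensemble with interpretable rule-path extraction and composite
    scoring of positive-diagnosis condition combinations, confusion-matrix
    evaluation of each combination, and triangulation by logistic regression
    including additive-scale interaction (RERI) with delta-method or bootstrap
    confidence intervals and within-stratum odds ratios. A synthetic cohort
    generator with sex-stratified condition prevalences and a latent
    grip-strength model with planted synergistic pair effects supports
    simulation studies and parameter-recovery testing, and a sensitivity suite
    reruns the pipeline under alternative grip-strength thresholds, doubled
    false-negative penalties and condition removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
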