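---
title: "Mining long-term condition combinations for sarcopenia risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining long-term condition combinations for sarcopenia risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People living with multimorbidity — two or more long-term conditions (LTC) —
have elevated risk of sarcopenia, the accelerated loss of muscle strength and
mass. Which *specific combinations* of conditions carry that risk is hard to
learn from conventional regression: from 53 candidate conditions there are
1378 pairs, 23,426 triples, and more than 10^10 combinations of up to ten
conditions, far beyond what an exhaustive screen with multiple-testing
control can handle. `sarcomb` implements a data-driven alternative:
interpretable decision-tree ensembles that propose combinations, followed by
conventional epidemiological estimation that vets them.

The pipeline, sex-stratified throughout because men and women have distinct
multimorbidity patterns:

1. **Outcome construction.** Sarcopenia risk is dichotomised maximum grip
   strength: at risk iff grip is strictly below 32 kg (men) or 19 kg (women),
   the cut-points two SDs below young-adult reference means. Participants
   unable to perform the test for health reasons are classified at risk.
   EWGSOP2 probable-sarcopenia thresholds (<27 kg / <16 kg) are packaged as a
   sensitivity preset.
2. **Sample definition.** Participants with at least two LTC and a
   classifiable outcome.
3. **Cost-sensitive trees.** Classification trees on the 53 binary condition
   indicators with Gini impurity, maximum depth 10 and minimum terminal-node
   size 25. Because the outcome is imbalanced (~1 in 5 at risk), false
   negatives are penalised by `(1 - p)/p` relative to false positives, the
   penalty derived directly from the outcome proportions `p`.
4. **Bagged rule extraction.** 1000 trees on bootstrap resamples; every
   root-to-leaf path ending in an at-risk leaf is collated; literals
   requiring the *absence* of a condition are disregarded, leaving a
   positive-diagnosis condition set per rule.
5. **Composite scoring.** Each distinct set is scored by summing, over all
   contributing leaves in the ensemble, the leaf's probability of correct
   classification — blending how often the combination appears with how well
   it classifies. The top 12 sets per sex are retained.
6. **Triangulation.** Each retained combination is re-estimated by logistic
   regression: per-condition odds ratios; for pairs, joint-exposure odds
   ratios, the relative excess risk due to interaction
   (RERI = OR11 − OR10 − OR01 + 1) with a delta-method CI, and
   within-stratum odds ratios in a Knol–VanderWeele-style layout.
7. **Sensitivity suite.** The pipeline is rerun under EWGSOP2 thresholds, a
   doubled false-negative penalty, and removal of hypertension (the most
   prevalent condition), and the top-12 overlap with the main analysis is
   reported.

## The tree learner

The unit the ensemble bags is a CART-style binary tree restricted to binary
features, written for this package:

* **Loss as altered priors.** The loss matrix enters as per-observation class
  weights (at-risk observations weigh `fn_penalty`, others `fp_penalty`),
  the standard CART equivalence for two classes. Node impurity is
  `2q(1 - q)` with `q` the weighted positive fraction; splits maximise the
  weighted impurity decrease.
* **Split acceptance.** A split is rejected if the node is pure or smaller
  than `min_split` (= 2 × the 25-observation bucket unless overridden), a
  child would fall under 25 observations, depth 10 is reached, or the gain
  does not exceed `complexity_penalty` × the root impurity.
  `complexity_penalty` defaults to 0 — growth is governed by the stated
  depth/size constraints; 0.01 is available to mimic the common
  recursive-partitioning default when cross-checking against `rpart`.
* **Determinism.** Ties in gain are broken by the lowest registry index, so
  a fitted tree is a pure function of its data; ensembles derive one child
  seed per tree from the master seed. Everything downstream is therefore
  byte-reproducible, and there is no thread-dependent state.
* **Leaf labels.** A leaf predicts at risk when its positive fraction exceeds
  `fp/(fp + fn)` — the minimum-expected-loss rule, not the 0.5 majority rule.

Tests verify the learner two independent ways: exhaustive enumeration of all
depth-≤2 trees on small random datasets (the greedy tree's expected loss is
always attainable by an enumerated tree, and almost always equals the
optimum when the root gain maximiser is unique), and agreement of training
expected loss with `rpart` under a matched loss matrix and controls. The
enumeration also documents the known gap between impurity-based and
loss-based splitting: a uniquely Gini-best root split is not guaranteed to
be the misclassification-loss-optimal root, and the suite retains one such
counterexample.

## Scoring interpretation

The composite score is stated verbally in the literature this package
implements ("summing the probability of a correct classification across the
ensemble"). Two readings were open; the package implements the plain sum of
leaf positive-predictive values on each tree's own bootstrap sample (in-bag),
with an out-of-bag variant available via `bootstrap_ensemble()`'s bookkeeping
of resample indices. A combination reached at several leaves of one tree
contributes once per leaf to the score but once per tree to its appearance
count, so "appearing in at least half the ensemble" counts trees, as
summaries of this kind conventionally do. The loss matrix is recomputed from
each bootstrap sample's own outcome proportions (it is defined *from the
proportions of the two outcomes*); `freeze_loss = TRUE` keeps the full-sample
matrix for every tree.

## The synthetic cohort generator

The study data this design targets are access-restricted, so the generator
provides cohorts with the statistical structure the analysis assumes:

* **Conditions.** Per-sex Bernoulli draws at a packaged calibration table of
  53 prevalences spanning 0.02%–67% (a UK population cohort of adults aged
  ~40–70), independent by default, or a thresholded latent-Gaussian copula
  when a dependence matrix is supplied. Endometriosis is structurally zero
  for men.
* **Grip.** `intercept(sex) − slope·(age − 40) − Σ main effects −
  Σ synergy effects + N(0, sd(sex))`, with intercepts/noise chosen to give
  mean grip near 23 kg (SD ~6.6) for women and 39 kg (SD ~9.3) for men and
  an at-risk fraction near 20–25% after restriction. Severe
  neurological/systemic conditions carry larger decrements (3–5 kg),
  everything else 1–2.5 kg. Age is uniform: the analysis uses age only as a
  covariate, so its distributional shape is immaterial to the properties
  under test.
* **Unable group.** A 0.12% uniform rate, grip then missing.
* **Planted synergy.** Pairs listed in `synergy_effects_kg` lose an extra
  decrement when both members are present. Because the outcome is a
  thresholded Gaussian, every planted pair has a well-defined true additive
  interaction that `true_pair_reri()` computes by Monte-Carlo integration
  (closed-form normal tail per draw, averaged within observed exposure cells
  of the multimorbidity-restricted population).

What the generator does *not* emulate: realistic comorbidity clustering
(unless a copula is configured), age-dependent prevalence, longitudinal
decline, and the nurse-interview coding process. Passing recovery tests
therefore show that the pipeline finds planted signal under its own
assumptions — not that it would find every clinically real signal.

## Scales for the interaction truth

`true_pair_reri()` reports the RERI on either the risk-ratio scale (risks
relative to the doubly-unexposed cell) or the odds-ratio scale (cell odds).
The logistic estimator targets the odds-ratio contrast; with a common
outcome (cell risks of 15–40% in the default calibrations) the two scales
differ materially, which is exactly the standard caveat about treating ORs
as risk-ratio approximations in RERI. The interval-coverage study therefore
benchmarks the delta-method CI against the odds-scale truth — the estimand
the estimator actually has — and the package prints the caveat alongside
RERI output in documentation. For rare outcomes the two scales converge.

## Problem sizes used by the packaged studies

* Planted-pair recovery: two pairs (diabetes × osteoarthritis, connective
  tissue disease × osteoporosis; 20 kg extra decrement), cohorts of 20,000
  women, 200-tree ensembles, 20 generator seeds; recovery means the exact
  pair ranks in the top 12. The female side is used because both pairs have
  joint prevalence there (~2.9% and ~0.4%) sufficient to form 25-observation
  leaves; the pairings highlighted in the motivating analysis for men
  (drug/alcohol misuse × osteoarthritis) have joint prevalence ~0.005%,
  below any attainable leaf at this sample size.
* Interval coverage: a reduced six-condition male configuration with one
  planted pair, 500 replicate cohorts of 20,000, truth from a 2×10^6-draw
  Monte-Carlo oracle.
* Tree-oracle equivalence: 100 random 60×4 binary datasets against full
  enumeration of depth-≤2 trees.

## Numerical and degenerate-input choices

* Thresholds are strict (`<`): a grip exactly at the cut-point is not at
  risk.
* Chi-squared descriptives use the Pearson statistic without continuity
  correction (large-sample use; a flag restores Yates).
* Missing grip without the "unable" flag is unclassifiable and excluded at
  restriction; the unable group is classified at risk.
* A bootstrap resample with a single outcome class yields a stump (logged),
  not an error; an all-negative-literal rule reduction is discarded and
  counted.
* Split gains must exceed the floor by a 10^-12 relative tolerance to guard
  against floating-point ties; gain ties resolve to the lowest registry
  index.
* PPV of an unexposed combination is reported missing; empty strata are
  reported missing with a reason rather than dropped silently.
* Condition removal in the sensitivity suite affects only the feature set
  and combination space — eligibility still counts the removed condition, so
  the analytic sample is identical to the main run's.

## Known limitations

* The composite score's exact functional form is an interpretation (plain
  in-bag sum); ranks can differ under out-of-bag scoring.
* RERI confidence intervals are delta-method Wald intervals by default;
  the percentile bootstrap is available and agrees in the packaged
  simulations, but both inherit the OR-vs-RR caveat above.
* The generator's independence default understates real comorbidity
  clustering; copula configurations are first-class but not calibrated to
  any external dataset.
* No multiple-testing correction is applied in triangulation (the number of
  tests is reported instead), mirroring the design this package reimplements.
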