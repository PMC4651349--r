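---
title: "Methods: scoring and evaluating the teen STOP-Bang instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and evaluating the teen STOP-Bang instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teenstopbang)
```

## The instrument

Obstructive sleep apnea (OSA) in children is under-diagnosed because
polysomnography is expensive and scarce. A count-based screen adapted from
the adult STOP-Bang questionnaire offers a cheap first pass for adolescents.
The instrument counts eight binary items:

* **S**noring, **T**iredness, **O**bserved apnea, academic problems — four
  questionnaire items answered by a parent or by the child on a six-level
  ordinal scale (*don't know, never, rarely, occasionally, frequently,
  almost always*). *Frequently* or *almost always* counts as positive;
  everything else, including *don't know*, is negative. The academic-problems
  item replaces the adult tool's age-over-50 item, since learning problems
  are a recognized correlate of sleep-disordered breathing in children.
* Blood **P**ressure at or above the 95th percentile for sex, age and
  height; **B**MI strictly above the 95th percentile for sex and age; neck
  circumference strictly above the 95th reference percentile for sex and
  age; male sex — four measured items.

The total runs 0–8 (`stop_bang`) or 0–7 for the neck-free `stop_bag`
variant, which matters because neck circumference is not a routine pediatric
office measurement. A total below 3 is read as low OSA risk; OSA itself is
operationalized as an apnea–hypopnea index (AHI) of at least 1.5 events per
hour of sleep on polysomnography (1 and 3 are supported as sensitivity
thresholds, as are BMI cuts of 90/95/99).

Child-reported scores use the child's questionnaire answers but the *same*
measured anthropometric flags and sex: only the questionnaire reporter
varies, because the measurements are made by staff, not reported.

## Reference percentiles

The measured items depend on pediatric growth references, which this
package treats as pluggable data (`reference_set()`):

* **BMI-for-age** uses the LMS (Box–Cox) parameterization standard in
  growth charts: `z = ((x/M)^L - 1)/(L S)` (log form at `L = 0`), with L, M
  and S interpolated *linearly in age* between tabulated rows — the usual
  growth-chart practice, and easy to test (continuity at knots,
  invertibility to 1e-9).
* **Blood pressure** uses the height-age regression structure familiar from
  pediatric BP guidelines: expected BP is an intercept plus fourth-degree
  polynomials in `(age - 10)` years and in the height-for-age z-score; the
  observed value (the mean of the 2nd and 3rd seated readings, averaged at
  data entry) is converted to a percentile via the residual SD. With all
  polynomial terms zeroed this collapses to a plain normal CDF, which the
  tests exploit as a closed-form limit.
* **Neck circumference** is a direct (sex, integer age) 95th-percentile
  lookup; decimal ages round to the nearest year because the reference is
  tabulated by year.

The **bundled default tables are synthetic**: smooth curves with realistic
magnitudes and age trends for ages ~8.5–18, shipped under
`inst/extdata/synthetic_*.csv`. They exercise the formulas and power the
simulation; they are not clinical reference data, and real tables can be
plugged in via `read_reference_set()`. Correctness claims attach to the
formulas given whatever tables are supplied. Percentiles are reported
uncapped; any display capping is a reporting choice, not a computation.

## Diagnostic accuracy

`build_contingency()` dichotomizes the score at a threshold (predicted
positive = score ≥ threshold) against the OSA label, and
`summary_table()` assembles the full panel across thresholds {2, 3, 4} and
age strata: sensitivity, specificity, PPV, NPV, LR+ = sens/(1−spec),
LR− = (1−sens)/spec, and the **prevalence-adjusted likelihood ratios**

\[ LR^{+}[P] = LR^{+} \cdot \frac{p}{1-p}, \qquad
   LR^{-}[P] = LR^{-} \cdot \frac{p}{1-p}, \]

i.e. the post-test *odds* of disease after a positive or negative result.
These equal `PPV/(1−PPV)` and `(1−NPV)/NPV` when the predictive values are
computed at the same prevalence via Bayes — an identity the test suite
asserts to 1e-12. Adjusted LRs default to the analyzed cohort's own
prevalence (one cohort-wide pre-test odds in every stratum), overridable.
With a prevalence near 0.08 this matters: a raw LR− of 0.4 corresponds to
post-test odds of only 0.04.

Confidence intervals: Wilson score intervals for proportions by default
(Clopper–Pearson by option — both cross-checked against closed forms), and
the log-method for likelihood ratios, with a +0.5 continuity correction and
an explicit flag when a cell is zero. Zero-denominator quantities are
returned as `NA` and flagged, never silently zeroed. Display rounding is
half-up at the conventional printed precision (1 decimal for LRs, 2 for
proportions); internal values are never rounded.

## ROC and AUC

The score is ordinal with heavy ties, so everything is tie-aware:

* the empirical ROC is a staircase with one operating point per distinct
  threshold plus (0,0)/(1,1) anchors;
* the AUC is computed two independent ways — midrank (Mann–Whitney
  pair-counting with 0.5 credit for ties) in the estimator, trapezoidal
  area under the staircase as the cross-check — and the suite requires
  agreement to 1e-12 on every input;
* the variance is DeLong's: per-case and per-control placement values with
  the midrank convention, `var(V10)/n1 + var(V01)/n0`; CIs are normal,
  truncated to [0, 1] with a flag. Paired comparisons (parent vs child
  reporter on the same subjects) subtract twice the placement covariance;
  stratum comparisons (teen vs preteen, high vs low sexual maturity) use
  the independent-samples z. Hanley–McNeil would give similar widths at
  these sizes; DeLong is the default because it is distribution-free under
  ties.

Simulation checks at study scale (n = 312, prevalence 0.08) put the DeLong
95% CI coverage at roughly 0.93–0.94 for generating AUCs of 0.6–0.8 —
slightly conservative-of-nominal from below, as expected with ~25 cases —
and the estimator unbiased to within 0.02.

## Auxiliary tests

Score distributions are skewed counts, so group comparisons are
nonparametric. The module wraps the standard R implementations behind a
stable surface with explicit mode control: Wilcoxon signed-rank (zeros
dropped before ranking — the classic rule, not Pratt's — exact enumeration
for tie-free n ≤ 12, else tie-corrected normal approximation with
continuity correction), Mann–Whitney U (exact when `n_x n_y ≤ 400` and
tie-free), and a one-sample Kolmogorov–Smirnov normality check against a
normal with estimated mean/SD (conservative; the Lilliefors-corrected
variant is an option). Exact modes are validated against full enumeration
oracles (all sign patterns; all rank assignments) in the tests. Quantiles
use linear interpolation (type 7), the common default when no convention is
stated.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a community adolescent cohort
so every analysis stage can be tested without any external data:

* n = 312, prevalence 0.08, ages uniform on 9–17 — the study-scale
  defaults;
* AHI from class-conditional lognormals (healthy median 0.2, truncated
  below the 1.5 cut; OSA median 2.2 = 1.5 + lognormal(median 0.7)), so
  labels and AHI are consistent by construction;
* the eight items are conditionally independent Bernoulli given status —
  the simplest generative model for a count score. Default probabilities
  are calibrated by binomial tail inversion (`calibrate_items()`) so that
  P(score ≥ 3 | OSA) = 0.64 and P(score ≥ 3 | healthy) = 0.18, a realistic
  adolescent operating point that also lands the score medians at 1
  (healthy) vs 3 (OSA). Because the score is then exactly binomial, the
  generating AUC is available in closed form (`binomial_score_auc()`,
  ≈ 0.80 at the defaults) for coverage studies;
* anthropometrics are *back-solved*: a measurement is placed a fixed offset
  above or below the relevant reference cutoff (BMI at the 97.5th vs 65th
  percentile; BP at +1.8 vs −0.2 residual SDs; neck at ±0.5 cm) so
  `anthropometric_flags()` reproduces the intended flags exactly. Flags,
  not raw measurement distributions, drive the score, so realism is spent
  where it matters;
* sex is driven by the male item flag (keeping the exchangeable calibration
  exact); `sex_ratio` takes over only when the male item probability is set
  `NA`;
* child responses copy the parent's per item with probability 0.8, else are
  resampled from the item's class-conditional law; self-reported sexual
  maturity follows a logistic in age centred at 13.5 years, missing in
  ~6.7% of records;
* one integer seed drives everything, and the RNG state is restored on
  exit.

What the generator deliberately does **not** emulate: correlations between
items (e.g. BMI–BP), ethnicity effects, measurement error in self-assessed
maturity, and realistic marginal distributions of the raw anthropometrics.
Passing tests therefore demonstrate the correctness and calibration of the
*estimation machinery* under a faithful count-score model, not the field
performance of the instrument on real children.

## Numerical and design choices

* Teen/preteen split at decimal age ≥ 13.0 exactly; maturity split at
  self-rating ≥ 4 with an explicit `unknown` stratum.
* Threshold ties: score ≥ threshold is elevated/predicted-positive
  throughout.
* Completeness filtering takes the reporter as a parameter (a record is
  analyzable for the parent analysis even if a child item is missing);
  missing responses are never imputed as negative.
* Response normalization folds case, whitespace and apostrophes
  ("Don't know" → `dont_know`); unknown strings fail parsing with the
  admissible vocabulary in the message.
* Simulation sizes in the tests (200 replicates for operating-point
  recovery at n = 176; 2000 for CI coverage at n = 312 and for type-I
  error at n = 30/group) were chosen so each study's own Monte Carlo error
  is small relative to the acceptance band it feeds.

## Limitations

The bundled references are synthetic, so absolute percentile values have no
clinical meaning out of the box. The generator's conditional-independence
assumption understates between-item correlation in real cohorts, which
would widen the score's variance; a correlation knob is future work. Exact
nonparametric modes fall back to asymptotics in the presence of ties, which
is the dominant case for ordinal scores — the tie-corrected approximation
is accurate at these sample sizes (|Δp| ≤ 0.02 at n = 12 in the suite) but
is still an approximation.
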