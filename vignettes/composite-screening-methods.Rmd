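---
title: "Methods: the composite SOC/GHQ screening indicator and its diagnostic evaluation"
author: "resilscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite SOC/GHQ screening indicator and its diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilscreen)
```

## The screening problem

Mental-health screening in student populations usually relies on a single
deficit-oriented instrument. The indicator implemented here instead crosses a
resource-oriented scale — Antonovsky's sense of coherence, measured by the
13-item SOC-13 (7-point items, total 13–91, higher = greater coherence) —
with a distress scale, the 12-item General Health Questionnaire (GHQ-12,
4-point items scored 0-0-1-1 so the total runs 0–12). Each scale is
dichotomized:

* **SOC**: "normal" is a total strictly above the upper-tertile cutpoint.
  The study population's cut is 65 points, which is the packaged fixed
  default; `classify_cohort(tertile = "empirical")` recomputes the
  nearest-rank 2/3 order statistic from the cohort at hand instead.
* **GHQ**: "high distress" is a total strictly above 4 (equivalently, 5 or
  more symptoms), the threshold used by the Hungarian national health
  interview survey.

The 2×2 cross gives four categories: **resilient** (normal SOC, normal GHQ),
**vulnerable** (low SOC, high GHQ), and two *non-classifiable* cells with
conflicting results (low SOC with normal GHQ; normal SOC with high GHQ).
Category prevalences are reported with Wilson score intervals
(no continuity correction); that choice reproduces the published 21.1% lower
bound for a vulnerable proportion of 0.251 at n = 399, so it is evidently
the interval the original analysis used.

## Diagnostic evaluation as a multi-level test

The indicator is evaluated against a binary reference standard — an at-risk
depression dichotomy from the 9-item Beck Depression Inventory short form
(bands: ≤9 none, 10–18 mild, 19–25 moderate, >25 severe; at-risk = total
strictly over 18), or dichotomized perceived health (good/very good versus
fair or worse). Because a 4-level test should not be collapsed to 2×2, the
package computes a **likelihood ratio per category**,

$$LR_c = \frac{P(c \mid D^+)}{P(c \mid D^-)},$$

with LR+ and LR− denoting the vulnerable and resilient categories. Post-test
probabilities follow from Bayes' rule on the odds scale:
pretest odds × LR, converted back to a probability. On the same
cross-table these coincide *exactly* with the count-based predictive values
(PPV for vulnerable-vs-rest, 1 − NPV for resilient-vs-rest); the test suite
asserts this identity to machine precision, and `bayes_pretest()` inverts
the relation so published (post-test, LR) pairs imply their pretest
prevalence.

Discrimination is summarized by the nonparametric AUC over the ordinal
categories: levels are ranked by ascending estimated LR (ties broken by
declaration order — the canonical risk ordering for a multi-level test;
in the study data the normal-SOC/high-GHQ cell has LR 0 and ranks below
resilient's 0.054), and the tie-corrected Mann–Whitney probability
$P(\text{rank}_{+} > \text{rank}_{-}) + \tfrac12 P(=)$ is computed exactly
from grouped counts. `auc_from_marginals()` reconstructs the same quantity
analytically from published marginals, LRs and prevalence, for settings
where only summary tables survive. The AUC interval uses the Hanley–McNeil
grouped-count standard error with a Wald interval clipped to [0, 1]; DeLong
would need per-subject predictor values that grouped tables do not carry.
Published AUC intervals are therefore compared only loosely, since their
method is typically unstated.

Degenerate levels are reported honestly rather than silently repaired: a
level seen only among reference-positives yields `Inf`, an empty level
`NaN`, and Haldane-style +0.5 smoothing is available but **off** by default,
because a raw zero count (no depressed student with normal SOC and high
GHQ) is itself a finding.

## Supporting statistics

* `two_sample_proportion_test()`: pooled-variance z, two-sided, for cohort
  versus general-population category prevalences; the packaged
  `general_population_reference()` table carries the published 18–25-year-old
  distribution (7.9 / 0 / 60.2 / 31.8 %).
* `contingency_test()`: Pearson chi-squared without continuity correction,
  switching to Fisher's exact test for 2×2 tables with any expected cell
  below 5 (overridable).
* No multiplicity adjustment is applied anywhere, matching the analysis
  being reproduced.

## Missingness

Scale scores follow a strict available-case rule: a total is missing when
*any* of its items is missing, and each analysis uses all respondents
complete for it. `little_mcar_test()` supports that choice: it estimates
the grand mean and covariance by EM under multivariate normality (tolerance
10⁻⁶ on the maximum parameter change, at most 500 iterations) and compares
each missingness pattern's observed means with the EM estimates via the
pattern-weighted chi-squared statistic. We enter scale totals and age — not
raw ordinal items — to keep the normality approximation tenable, and treat
ordinal totals as numeric (a documented approximation). Monte-Carlo checks
in the suite confirm the nominal type-I error under MCAR and substantial
power against a strong MAR mechanism at n = 500.

## Synthetic cohorts

No raw data accompany the published analysis, so the package generates its
own, at two fidelity levels.

**Category-level** (`generate_category_cohort()`): categories are drawn
multinomially from the published marginals (0.251, 0.023, 0.442, 0.284) and
the depression label Bernoulli with the category-conditional posterior
$p\,LR_c/(p\,LR_c + 1 - p)$, using prevalence p = 0.207 — obtained by
inverting the published pair (post-test 0.405, LR+ 2.61), since the
depressed fraction is never printed directly. This is the exact-expectation
surface for testing the estimators. One caveat is recorded here because it
matters for interpretation: the published rounded marginals and LRs are not
mutually consistent (the implied $P(c \mid D^+)$ sum to 0.970, and the
implied marginal prevalence is 0.2007 rather than 0.207), so the empirical
cross-table LR of the vulnerable level has expectation ≈ 2.71, not 2.61.
The generator deliberately reproduces the published recipe rather than
projecting the inputs onto consistency.

**Item-level** (`generate_item_cohort()`): a single latent resilience factor
L ~ N(0,1) drives every item through $y^* = aL + e$, $e \sim N(0,1)$, cut at
per-instrument thresholds (shared within an instrument block — exchangeable
items are sufficient to control the score distributions the pipeline
consumes, though real items differ in difficulty and loading). SOC items
load positively, GHQ/BDI/health items negatively; the five canonical
reverse-keyed SOC items are emitted reverse-coded so default scoring keying
round-trips. A single factor is the simplest structure consistent with the
strong negative SOC–GHQ association the composite assumes; it is a modeling
convenience, not a claim about any real population, and it cannot reproduce
all four category LRs simultaneously (the resilient-level LR comes out
larger than the published 0.054). Missingness is MCAR at a configurable
rate (default 2%, within the "under 5% per variable" regime the
available-case analysis assumes); real questionnaire missingness is rarely
exactly MCAR.

**Calibration** (`calibrate_latent()`): deterministic given its seed, using
common random numbers (one draw of latents and noise reused across all
candidate evaluations, so the objective is smooth and bisection is valid).
Stage 1 grids the SOC/GHQ loading magnitude (the 2×2 dependence dial) and
bisects the two threshold shifts to the category marginals; stage 2 bisects
the BDI loading (LR dial) with its threshold shift pinned to the target
prevalence; finally the logistic depression link is recovered by regression
of the calibrated BDI dichotomy on the latent. Calibration at n = 20,000
reaches the published category proportions within 0.005 and the vulnerable
LR within 0.05 — comfortably inside the 0.03 / 0.4 acceptance bands — in
about 16 candidate evaluations (~5 s).

## Pipeline and reproducibility

`run_pipeline()` is a pure function of (input, config): respondents
answering less than a quarter of the questionnaire are excluded with a
logged reason, everything else flows through scoring → classification →
prevalence summary → diagnostic evaluation → missingness report, and a
manifest (config hash, package version, seed, exclusion counts) makes reruns
checkable byte for byte. All generators take explicit seeds and restore the
global RNG state, so nothing in the package consumes shared randomness.

Problem sizes used by the test suite were chosen to keep Monte-Carlo error
well inside the asserted bands: 200,000 subjects for category-level
expectation checks (binomial SE < 0.0011 on any proportion), 20,000 for
calibration and pipeline closure, 200 replicates for the MCAR type-I
calibration, and 1,000 random tables for the brute-force oracle sweeps.

## Known limitations

* SOC-13 item polarities and the BDI-9 per-item response range are not part
  of the published record; the canonical reversal set {1, 2, 3, 7, 10} and
  items coded 0–3 are package defaults, both overridable.
* A BDI total of exactly 9 is assigned to the "none" band (the published
  bands "below 9" and "10 to 18" leave 9 unassigned; 9 is below the mild
  floor).
* The single-factor latent generator matches marginals and the vulnerable
  LR, not the full joint distribution of a real cohort; passing closure
  tests show the pipeline's internal consistency, not field validity.
* Statistics requiring the raw study data (mean age, sex-difference p-value,
  the original Little's-test p, GHQ-alone/SOC-alone predictive values, AUC
  confidence bounds) are out of reach by construction and are not asserted.
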