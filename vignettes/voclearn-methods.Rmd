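---
title: "Discovering discriminating urinary VOCs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering discriminating urinary VOCs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`voclearn` implements a complete biomarker-discovery workflow for two-group
SPME GC-MS urine profiling studies: from triplicate peak-area tables to a set
of putative volatile organic compound (VOC) markers separating, for example,
overweight/obese from normal-weight children. This vignette explains the
statistical machinery, the tunable parameters, and the design decisions taken
where the methodology left genuine choices open.

## The data and its preprocessing

A study of this kind produces, per headspace pH condition, a table of peak
areas: one row per injection (each subject contributes technical replicates,
typically triplicates), one column per VOC feature plus the spiked internal
standards. The preprocessing chain is fixed in this order:

1. **Internal-standard ratio** (`normalize_to_internal_standard()`): each
   feature's peak area is divided by the mapped internal-standard peak area
   of the same injection, removing injection-to-injection extraction and
   detector drift. Which of the six standards normalises which metabolite is
   chemistry-dependent and is supplied by the user as a mapping; the
   synthetic generator uses a round-robin mapping.
2. **Median of replicates** (`collapse_replicates()`): robust against a
   single aberrant injection; a value is missing only if all replicates are.
3. **Missing-value handling**: occurrence below 100% means the compound was
   not detected in some subjects. The default policy replaces a missing cell
   by half the feature's minimum observed value — the usual detection-floor
   convention in GC-MS — with `drop_feature` available for sensitivity
   analyses.
4. **Log transform and autoscaling** (`log_autoscale()`): peak-area ratios
   are right-skewed and roughly log-normal; after the natural log each
   feature is centred and scaled to unit sample SD (n − 1 denominator), so
   every VOC enters the multivariate models with equal a-priori weight.
   Features constant or entirely missing are dropped with a warning, never
   an error.

The per-feature t statistics are invariant to the affine autoscaling and the
AUCs to any monotone transform, so the univariate battery is computed on the
log-scale matrix (kept as an attribute of the processed table) purely for
interpretability of effect directions.

## Outlier screening

Before modelling, a PCA of the autoscaled matrix is screened with the two
complementary statistics at a 95% level: Hotelling's T² (distance within the
model plane, F-limit with `A` and `n − A` degrees of freedom) and DModX (the
per-subject residual SD normalised by the pooled residual SD, with an F-based
limit on `p − A` and `(n − A − 1)(p − A)` degrees of freedom). The exact
DModX degrees-of-freedom convention varies across chemometrics software
lineages; the one implemented here flags close to the nominal 5% of
multivariate-normal subjects (checked by simulation in the test suite). By
default the screen reports without excluding; `remove_outliers = TRUE`
re-runs the models without flagged subjects.

## PLS-DA, VIP and the post-transformation

The discriminant model is single-response PLS1 (NIPALS) on the class encoded
−1/+1: components maximise covariance between the feature space and the
class, `B = W (P'W)⁻¹ c` gives the regression vector, and R²Y is the
explained class variance. The number of components defaults to the smallest
`A ≤ 5` maximising cross-validated Q².

Feature influence is summarised by the standard VIP score,

$$\mathrm{VIP}_j = \sqrt{\; p \cdot \sum_a \mathrm{SSY}_a\,(w_{ja}/\lVert w_a\rVert)^2 \Big/ \sum_a \mathrm{SSY}_a \;},$$

whose squared values average to one, making 1 the natural "average
influence" threshold region.

For interpretation, a fitted model can be **post-transformed**
(`post_transform()`): the score space is rotated by an orthogonal matrix
whose first direction is `T'y/‖T'y‖`, so a single component carries all
covariance with the class and the remaining components are exactly
class-orthogonal. Because NIPALS scores are mutually orthogonal this
y-orthogonality is exact, the rotation preserves the score-space Gramian,
and predictions are untouched — the tests assert invariance to 1e-8 on
held-out rows. The score scatter of `autoplot()` then shows between-group
separation purely along the x axis.

## Validation: Q², cross-validated AUC, permutation test

Q² is computed SIMCA-style as `1 − PRESS/TSS` with a single PRESS pooled
over the concatenated held-out predictions of a stratified 7-fold
cross-validation (not per-fold averaging). The held-out continuous
predictions also yield a cross-validated AUC. This AUC is deliberately *not*
oriented: under the null it fluctuates around 0.5 and can drop below it,
which keeps null distributions honest.

Model validity is assessed by a label-permutation test: the full
cross-validation pipeline is re-run inside every permutation and the
exceedance p-value is `(1 + #{null ≥ observed})/(1 + n_perm)`. Its type-I
error is verified by simulation to sit inside the binomial 95% band around
5% (200 null cohorts, 99 permutations each).

## Monte-Carlo stability selection

`stability_select()` wraps VIP-based variable selection in Monte-Carlo
subsampling: in each of `n_subsamples` rounds (default 300; the calibration
and recovery simulations in the tests use 100) every subject enters with
probability 0.70; a PLS-DA model is fitted on the subsample; the VIP cutoff
is chosen from the grid {0.8, 0.9, 1.0, 1.1, 1.2, 1.5} by maximising 7-fold
Q² restricted to the surviving features; and a model refitted on those
features predicts the *excluded* subjects, giving one out-of-subsample AUC
per round (rounds whose excluded set misses a class contribute no AUC and
are counted). The per-feature selection frequency and the AUC distribution
(median and 5th percentile) summarise the run. The methodology literature
says only "most frequently selected"; the default frequency cutoff is 0.5
and the full frequency vector is always reported, so any other cutoff can be
applied transparently. The grid is a design choice: it brackets the VIP = 1
average-influence point, and the criterion (maximise Q²) is what the
original procedure prescribes.

## Univariate battery and the merge rule

Per feature, `univariate_stats()` reports the Welch t-test p-value, a
false-discovery-rate q-value (Storey's smoother estimate of the null
proportion by default, Benjamini–Hochberg available), the oriented
concordance AUC with a DeLong 95% CI (percentile bootstrap as fallback),
sensitivity and specificity at the Youden-optimal cutpoint (ties broken
toward specificity), post-hoc powers for the observed mean difference
(noncentral-t) and the observed AUC (Hanley–McNeil variance), and the
direction of the difference. Note that the DeLong interval is
anti-conservative for very small groups (it reaches nominal coverage around
40 subjects per group in our simulations); the bootstrap option is the safer
choice below that.

A feature becomes a putative marker (`merge_selections()`) if it is selected
by stability selection **or** passes the univariate gate `p < 0.05`,
`q < 0.1`, `AUC > 0.50`. The union matters in practice: features can be
multivariately stable yet individually borderline, and vice versa.

### The validity gate

One behaviour deserves emphasis. On a *null* cohort the chance correlations
between features and labels are properties of the fixed dataset, so they
persist across 0.70-subsamples: some noise features always reach high
selection frequency, and no frequency cutoff can distinguish them from real
signal using the same data. Stability selection controls stability under
subsampling, not the familywise error of the study. The pipeline therefore
admits multivariate selections to the marker set only when the PLS-DA model
passes the class-response permutation test (`validity_alpha = 0.05`); a
failed test — the expected outcome on an uninformative condition, as in an
acid-pH profile that separates nothing — leaves only the FDR-controlled
univariate arm. This mirrors how a discriminant model that fails permutation
validation is treated as a negative result rather than mined for markers.

## The synthetic cohort generator

Because raw cohort data of this kind are typically not public, the package
ships a generator (`generate_cohort()`) that emulates the statistical
structure the analysis assumes, and every claim the test suite makes is a
claim about data of this structure:

* two groups (defaults 28 and 21 subjects — labelled NW and OW/Ob — with 83
  features as in an alkaline-condition profile);
* per-feature log-normal abundances, log-mean uniform in [1, 4] and log-SD
  uniform in [0.3, 1.0], matching right-skewed peak-area ratios;
* informative features shifted in the second group by `effect_size`
  feature-log-SDs *before* replicate noise, so the signal must survive the
  median-of-triplicates step; the default `effect_size = 1.5` is a free
  demonstration parameter — published studies of this design do not report
  marker effect sizes on any comparable scale — and the recovery simulations
  use 2;
* per-subject presence/absence with configurable occurrence probabilities
  (absence is a true missing value, exercising the imputation policy);
* six always-present internal-standard channels with no group effect and 5%
  log-SD, mirroring a six-compound spike;
* multiplicative replicate noise with 15% CV by default, a typical
  technical-replicate CV for SPME GC-MS peak areas.

What the generator does **not** emulate: retention-time structure, censoring
that depends on abundance (absence is independent of level), correlated
metabolite blocks, batch or sequence drift, and non-log-normal tails. A
passing recovery test therefore shows the pipeline recovers planted signal
under clean assumptions; it does not certify behaviour under correlated or
drifting real-world data.

## Numerical and degenerate-input choices

* NIPALS stops early (with a warning downstream) when `X'y` or a score norm
  falls below 1e-12; requesting more components than `min(n − 1, p)`
  truncates with a warning.
* Cross-validation folds are stratified by class and dealt round-robin over
  the concatenated class-shuffled subjects, so `k = n` is exactly
  leave-one-out; a fold that would lose a class raises an error.
* Stability subsamples missing a class are redrawn (counted and capped);
  with `n_subsamples = 1, inclusion_prob = 1` the procedure degenerates to a
  single full-data fit with an empty AUC distribution, flagged by a message.
* All tied values in the Youden scan give J = 0 at both trivial operating
  points; the specificity-favouring tie-break returns sens 0 / spec 1.
* Storey's π₀ smoother is clamped to [1/m, 1] and falls back to the minimum
  raw estimate if the spline fails (relevant for very short p-value
  vectors).
* The Kovats retention-index helper defaults to linear (van den Dool)
  interpolation because temperature-programmed GC makes retention times
  approximately linear in carbon number; the logarithmic isothermal form is
  available.
* Welch's t is used for summary-statistics comparisons of cohort tables; it
  reproduces the printed Age and HOMA-IR p-values of the packaged cohort
  fixture at printed precision. (The fixture's Height row reproduces under
  neither Welch nor pooled t from the printed summaries — p-values of such
  tables are typically computed from raw data, so no agreement is forced.)
* The packaged marker-table fixture prints only the AUC 95% CI; where the
  merge-rule worked example needs the point AUC, the CI midpoint stands in.

## Problem sizes used by the checks

The simulation-based checks run at deliberately moderate sizes chosen to
give stable Monte-Carlo estimates: 200 null cohorts × 99 permutations for
type-I calibration; 5 × 500 subjects for outlier-screen calibration; 50
seeds × 100 stability subsamples for recovery and null-emptiness rates. The
full-size defaults (300 subsamples, 1000 permutations) remain the
recommendation for real analyses.

## Limitations

* PLS1 with two classes only; no multi-class or kernel variants.
* Stability selection inherits the single-dataset caveat above; external
  validation on an independent cohort is the only real guard against
  dataset-specific selection.
* Post-hoc power numbers describe the observed effect at the observed n;
  they are reported because such tables conventionally include them, not as
  a substitute for prospective power analysis.
* The q-value's π₀ estimate is unstable for fewer than a few dozen features;
  use `method = "bh"` there.
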