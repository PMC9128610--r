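---
title: "A two-group untargeted metabolomics workflow: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-group untargeted metabolomics workflow: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboflow)
```

`metaboflow` implements the statistical core of a two-group (control vs
high-fat-diet, "NC" vs "HFD") untargeted LC-MS metabolomics study across two
biofluids (plasma, urine), two electrospray ion modes and three time points,
together with a synthetic data generator whose ground truth makes every stage
testable. This vignette documents the models, the conventions that are easy
to get silently wrong, and the deliberate design decisions — including the
generator's limitations.

## The data model

A `feature_table` is a dense samples × metabolites matrix of non-negative
peak intensities plus group, fluid, ion mode and week. Missing values are
rejected rather than imputed: the peak-extraction output this models is
complete, so a hole is a data error. Auxiliary inputs are an annotation
table (compound name, endogenous/exogenous origin, superclass), GMT pathway
sets, and per-animal phenotype tables in three categories (physical,
blood-routine, serum-biochemistry). All writers serialize floats with 17
significant digits so a write/read round trip is bit-exact.

## Preprocessing

Two transforms, applied in this order before modeling:

* **Sum-normalization**: each sample's intensities are rescaled to sum
  to one, removing gross loading differences. It is idempotent, and it
  presumes the summed signal is group-invariant — see the generator notes
  below for what happens when that assumption is violated.
* **Pareto scaling**: each feature is centered and divided by the square
  root of its standard deviation, the common middle ground between no
  scaling (dominated by abundant features) and unit-variance scaling
  (noise-inflating). Constant features map to zero with a warning.

Univariate p-values and fold changes are always computed on the
sum-normalized (not Pareto-scaled) matrix: Pareto scaling destroys ratios.

A third transform, the **z-score profile** used for pathway trajectories,
follows this workflow's printed convention of dividing by the sample
*variance* rather than the standard deviation:

```{r}
zscore_profile(c(0, 2))                      # variance denominator (default)
zscore_profile(c(0, 2), denominator = "sd")  # conventional z-score
```

The variance convention changes the scale but not the shape of a
trajectory, so clustering and monotonicity are unaffected; the `"sd"`
switch is provided for the conventional reading.

## OPLS-DA

The supervised model is a from-scratch single-response O-PLS: the class
vector is coded as a centered ±1 response `y`; class-orthogonal components
are peeled off one at a time (weight `w ∝ X'y`, scores `t = Xw`, loadings
`p`, orthogonal weight `w_o = p − (w'p)w` normalized, deflation
`X ← X − t_o p_o'`), and a final one-component PLS is fit on the deflated
matrix. Predictions on new data remove the training orthogonal components
first. With `n_orthogonal = "auto"`, components are added while
cross-validated Q2 improves by at least 0.01 (cap 3).

Model quality is summarized by:

* **R2Y** — fraction of class-response variance explained in-sample;
* **Q2** — `1 − PRESS/TSS` over seeded, stratified 7-fold cross-validation
  (with n = 9 per group the folds hold 2–3 samples; a fold that would
  remove an entire class is an error, not a silent skip);
* **permutation p-values** for both, with the add-one rule
  `p = (1 + #{perm ≥ obs}) / (1 + n)` so p is never exactly zero.

**VIP** (variable importance for the projection) is
`VIP_j = sqrt(p · Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`; with the single
predictive component this reduces to `sqrt(p)·|w_j|/||w||`, and in every
mode the mean of squared VIPs is exactly 1. Two properties of VIP matter
for interpretation:

1. It is *abundance-weighted* under Pareto scaling: the predictive weight of
   a feature scales with the square root of its raw abundance, so a
   genuinely differential low-abundance metabolite can sit just below
   VIP = 1 while carrying a tiny univariate p-value.
2. It is *scale-relative* (the mean-square-1 normalization): making every
   effect in a dataset stronger does not raise any feature's VIP relative
   to the others.

Both are faithful properties of the standard VIP > 1 screening rule, not
implementation artifacts; the acceptance suite documents a concrete case
where the rule misses a real effect for exactly this reason.

## Differential screening

A metabolite is called differential when **VIP > 1 and raw univariate
p < 0.05** — deliberately unadjusted, mirroring the common practice this
workflow models. The univariate test is normality-gated: Welch's t-test if
both groups pass Shapiro-Wilk at 0.05, Mann-Whitney otherwise. Ion modes
are screened separately and merged afterwards, deduplicating by compound
name and keeping the smaller p-value; annotations then classify each hit as
endogenous or exogenous.

## Pathway analysis

Over-representation is a one-sided hypergeometric test of the differential
set against the detected background, BH-adjusted across pathways. The
**DA (differential-abundance) score** summarizes direction:
members measured in the table get Mann-Whitney p-values, BH-corrected
within the pathway; the score is
`(n_increased − n_decreased) / n_measured`, so +1 means every measured
member rose significantly in HFD and −1 that every member fell. The score
is antisymmetric under label swap and bounded in [−1, 1] by construction.

## Trend clustering

Each pathway becomes a three-point trajectory: every metabolite is z-scored
across *all* samples of *all* time points (shared scaling keeps levels
comparable over time), and the pathway's value at a week is the mean member
z-score over the HFD samples. Trajectories are K-means clustered (k = 8,
seeded, best of 50 restarts), and clusters whose centroid is *strictly*
monotone across all three time points are flagged up/down. Strict — not
weak — monotonicity is deliberate: with three points, weak monotonicity
would flag essentially flat centroids. The flip side is that a cluster of
genuinely flat trajectories still has about a 1-in-6 chance of a strictly
ordered noisy centroid, so "the monotone clusters" are interpreted as
*containing* the true trends, not as equal to them.

## Phenotype correlation and the cross-fluid conjoint

Metabolite-phenotype association is plain Pearson correlation with
raw-p significance tiers (`*` < 0.05, `**` < 0.01, `***` < 0.001) and a
Venn-style intersection of the three phenotype categories. For metabolites
detected in both fluids, the conjoint analysis computes the cross-animal
plasma-urine correlation (flagged when |r| > 0.4 and p < 0.05) and a
concordance class from the two fluids' screening directions: concordant-up,
concordant-down, discordant, or unclassified.

## The synthetic generator

`simulation_spec()` defaults *are* the modeled study conditions: 9 animals
per group, 1295 plasma / 1868 urine features, 540 shared metabolites with 8
concordant-up, 4 concordant-down and 2 discordant injected classes, ~12%
differential features at a typical two-fold multiplicative effect, weeks
0/12/24 with effects absent at baseline, 40 pathways of which 4 + 4 trend
monotonically, and phenotypes mixed to target correlations from their driver
metabolites. Intensities are log-normal; three design decisions deserve
explanation because each was forced by a failure mode discovered while
validating the generator against its own truth:

* **Per-ion-mode mass balancing.** Sum-normalization assumes the total
  signal is group-invariant. Injecting unbalanced differential effects
  shifts the HFD row totals of the affected mode, and normalization then
  smears a small coherent *opposite* shift across every null feature — at
  worst producing spurious "concordant" calls in both fluids at once.
  Fill-effect directions are therefore assigned greedily to cancel the
  expected total-signal shift *within each ion mode* (the unit on which
  normalization operates).
* **Fluid-exclusive fill differentials.** Non-class differential
  metabolites are drawn from names detected in one fluid only, so the
  injected classes are, by construction, the only names that can be truly
  differential in both fluids and the concordance truth table is complete.
* **Shared-drift trends.** Trend-pathway members drift over time in *both*
  groups, keeping trajectories monotone in the analyzed group without ever
  confounding the two-group contrast (an HFD-only drift would silently turn
  "null" metabolites into differential ones at later weeks).

Cross-fluid coupling of class metabolites is variance-preserving (a shared
latent carries a fraction r = 0.85 of the within-sample log variance), so
coupled metabolites remain exactly as detectable as uncoupled ones.

**What the generator does not emulate.** Real LC-MS feature tables span
several decades of abundance; the generator's base-intensity spread
(log-SD 0.5) covers roughly one. This is deliberate: with a wide spread,
sum-normalization degenerates at desk scale (single features carrying a
large share of the total signal) and VIP — abundance-weighted, as noted
above — becomes blind to low-abundance true positives for reasons unrelated
to the statistics under test. On real data, expect the VIP > 1 rule to be
systematically less sensitive to low-abundance and decreased metabolites
than these simulations suggest. Missing values, batch effects, and
retention-time drift are out of scope.

Test-suite fixtures run at reduced sizes (tens to hundreds of features,
99 permutations) chosen as the smallest geometries at which the calibration
and recovery properties are meaningful; those sizes are this package's own
choice, not a property of the method.

## Reproducibility

Every stochastic step derives its seed from one run seed via
`stage_seed()`, RNG state is saved and restored around each seeded
computation, and all writers are full-precision, so `run_pipeline()` reruns
are byte-identical:

```{r}
st <- simulate_study(simulation_spec(
  n_per_group = 9, n_features = c(plasma = 60, urine = 50), n_shared = 20,
  n_concordant_up = 2, n_concordant_down = 2, n_discordant = 1,
  n_trend_up = 2, n_trend_down = 2, n_pathways = 8,
  pathway_size_range = c(3, 10), rng_seed = 7))
cfg <- analysis_config(rng_seed = 7, kmeans_k = 4)
m1 <- run_pipeline(st, cfg, tempfile(), permutations = FALSE)
m2 <- run_pipeline(st, cfg, tempfile(), permutations = FALSE)
identical(m1$outputs, m2$outputs)   # md5 digests of every output file
```
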