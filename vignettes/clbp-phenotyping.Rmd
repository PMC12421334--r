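---
title: "Sex-stratified biopsychosocial phenotyping of chronic low back pain: methods"
author: "clbpmca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified biopsychosocial phenotyping of chronic low back pain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clbpmca)
```

## The problem and the modelling strategy

Chronic low back pain (cLBP) in working populations is shaped by an
interacting web of biophysical, psychological and social factors. Rather
than fitting regression models — which multicollinearity among the many
psychosocial scores would undermine — this package summarizes the
*interrelationships* among the variables: questionnaire scores are
categorized into ordered modalities, the subjects-by-modalities table is
analysed by Multiple Correspondence Analysis (MCA), and the proximity
structure of the modality cloud is summarized by clustering, with special
attention to the modalities marking the *worst* cLBP state. Because score
distributions differ between men and women, every data-driven step
(categorization cut-points, MCA, clustering) is run separately per sex.

The pipeline stages, in order, are:

1. **Derived variables** (`derive_variables()`): BMI from weight/height
   and its WHO class; DN4-based pain-type adjudication; the binary
   *neuropathic features* composite (neuropathic or mixed type); the
   eligibility flag (average BPI severity item > 30/100 for >= 3 months).
2. **Categorization** (`build_scheme()`, `apply_scheme()`): each numeric
   variable becomes an ordered nominal variable, by referenced cut-offs
   (REF), empirical terciles (TER), or density-valley cut-offs for
   multimodal distributions (MM).
3. **MCA** (`build_indicator()`, `run_mca()`): correspondence analysis of
   the indicator matrix, with raw and Benzécri-adjusted inertia rates, and
   axis retention by adjusted share (`select_axes()`).
4. **Consensus clustering** (`cluster_modalities()`): Ward hierarchical,
   k-means and optimal univariate (Fisher dynamic-programming)
   partitioning of the modality coordinates; the *final cluster* is the
   intersection, over the three methods, of the clusters containing the
   anchor modality — the highest pain-interference tercile.
5. **Statistics** (`compare_numeric()`, `compare_nominal()`,
   `spearman_matrix()`, `work_factor_associations()`): the descriptive and
   comparative layer with explicit, reproducible test-selection rules.

## Pain-type adjudication

The DN4-based rules are applied in a fixed precedence order: incomplete
DN4 → *undefined*; DN4 at or above the positivity cut-off (default 4/10,
the standard published threshold, exposed as a parameter) →
*neuropathic*; typical neuropathic symptoms despite a negative DN4 →
*mixed*; widespread pain → *nociplastic*; otherwise *nociceptive*. A case
that is both mixed and widespread is classified mixed: nociplastic is the
fallback for widespread pain alone, matching the order in which the rules
are stated clinically. *Neuropathic features* is true for neuropathic or
mixed types.

## Categorization rules

REF rules are fixed and sex-invariant: WHO BMI classes (`< 25` normal,
`[25, 30[` overweight, `>= 30` obesity), HADS anxiety and depression
(`< 8 / [8, 11] / > 11`), TSK kinesiophobia (positive at `>= 40`), the
printed physical-activity split (`<= 1` h/week low, `2–3` moderate,
`>= 4` high) and the weekly-hours split (`< 30` part-time). TER and MM
rules are computed from the sex subsample.

Numerical choices that matter:

* **Quantile definition.** Terciles use the inclusive empirical quantile
  (type 1), so cut-points are values attained in the data — the
  convention that yields integer cut-points for integer-valued
  questionnaire totals. Classes are `< c1 / [c1, c2] / > c2` (closed
  middle), so ties at a cut go with the middle class.
* **Boundary policies.** Each cut-point carries its own tie policy, so
  both printed bracket dialects — closed `[a–b]` and half-open `[a–b[` —
  are representable and applied exactly.
* **MM detection.** Gaussian kernel density (Silverman bandwidth,
  512-point grid); cut-points at local minima between peaks, at the
  midpoint of the argmin set when the valley is flat. Two guards make the
  algorithmic version of an "by eye on the scattergram" judgement robust:
  peaks below 10% of the tallest are ignored, and adjacent peaks whose
  separating valley dips less than 20% below the lower peak are merged
  (KDEs of unimodal samples routinely show such wiggles). A unimodal
  verdict falls back to terciles.
* **Disorder grades.** Every modality carries a grade
  (low/intermediate/high/none): the worse pole is the 3rd tercile for
  pain, stress, catastrophizing and fear-avoidance scores, the 1st
  tercile for quality of life and physical activity, obesity, positive
  kinesiophobia and present neuropathic features. The grade drives the
  anchor choice and the map shading; work-description variables
  (seniority, weekly hours) are ungraded.

## MCA: model and conventions

With `Z` the n x J indicator matrix over Q active variables,
`P = Z/(nQ)`, row masses `r`, column masses `c`, the SVD of
`S = Dr^(-1/2)(P - rc')Dc^(-1/2)` yields principal inertias
`lambda_k` (squared singular values; total `J/Q - 1`), modality principal
coordinates `Dc^(-1/2) V sqrt(lambda)` and subject principal coordinates
satisfying the transition identity (a subject sits at the mean of its
modalities' standard coordinates). Contributions are
`c_j g_jk^2 / lambda_k`.

Raw indicator-MCA inertia percentages are pessimistic by construction, so
the Benzécri adjustment is always computed alongside:
`lambda' = (Q/(Q-1))^2 (lambda - 1/Q)^2` for `lambda > 1/Q`, with axes at
or below `1/Q` getting 0%. The *adjusted* share is the default display
and drives axis retention (threshold 5% marginal share, with a two-axis
floor since the modality maps are two-dimensional). Axis signs are fixed
deterministically by requiring the anchor modality to have non-negative
coordinates, so the worst-state pole of F1 is always on the positive
side and runs are comparable.

Empty modalities (declared by a rule but never observed) are dropped with
a warning. Rank-deficient inputs simply report fewer axes.

## Consensus clustering

Ward (minimum-variance, Euclidean) and k-means run on the retained
principal coordinates (F1, F2 in practice); the univariate partition runs
on F1 alone, via exact dynamic programming over contiguous splits —
the optimal 1-D analogue of k-means. Defaults: `k = 3` for all three
methods (exposed as a parameter; a silhouette sweep over k in 2..6 on the
synthetic maps picks no consistent value, so the conventional
low/central/high-disorder structure motivates 3); k-means uses 50 random
starts under a fixed seed (20250904) and is fully deterministic.

The final cluster is a *set intersection*: a modality belongs to it only
if every method places it with the anchor. It therefore shrinks (never
grows) as methods are added, is invariant to cluster relabelling, and is
reported in order of Euclidean distance to the anchor.

## The synthetic cohort generator

No subject-level survey data are shipped, so the generator stands in for
them. Each subject carries a single latent disorder factor
`z ~ N(0, 1)`; every numeric variable is
`mu + sd * (a z + s e) / sqrt(a^2 + s^2)` with loading `a`, noise scale
`s` (`noise_sd`, default 0.5) and independent `e ~ N(0, 1)`, rounded to
the instrument's granularity (integers for questionnaire totals, 0.1 for
BPI composites) and clipped to its bounds — clipping rather than
resampling, so the induced boundary mass is visible and documented. The
standardization keeps each variable's marginal location and scale at the
registry values (medians and quartile spreads of a service-company cLBP
workforce, per sex), whatever the loading; the correlation induced
between two variables is `a1 a2 / sqrt((a1^2+s^2)(a2^2+s^2))` before
discretization.

Neuropathic features follow a logistic link in the latent factor,
`P = plogis(alpha + beta z)` with slope `beta = 2` (a strong, clinically
plausible association between overall disorder severity and positive
neuropathic screening; only the direction of the association is known, so
the magnitude is an assumption and a config field) and the intercept
solved so the marginal rate equals 28.9%. The DN4 fields are then
assembled so the adjudication rules reproduce that flag: 10/74 of
flagged cases DN4-positive, the rest mixed; incomplete DN4 (7.4%) and
widespread pain (5.1%) rates among the remainder match the published
sample composition. Gesture, rest-day and sick-leave flags are Bernoulli
draws at the sex-specific prevalences. Eligibility is imposed by
truncation of the 0–100 average-pain item for a configurable fraction
(default: all subjects, matching an analysis-ready sample).

The two presets encode the sex-specific phenotypes as loadings of 0.85
(0.90 for pain interference, the anchor variable) on **exactly** the
variables whose worst modality belongs to each sex's final cluster —
women: catastrophizing, fear/avoidance towards work and physical
activity, stress at work, pain severity, kinesiophobia, physical QoL
(negative); men: catastrophizing, fear/avoidance towards work, pain
severity, anxiety, depression, mental QoL (negative) — and 0 elsewhere.
These magnitudes are assumptions, not estimates (no inter-variable effect
sizes are published), chosen once to produce a strong but not degenerate
one-factor structure.

**What the generator does not emulate:** item-level responses (totals
only), longitudinal trajectories, non-ignorable missingness, residual
correlations beyond the single shared factor (given `z`, variables are
conditionally independent — real anxiety/depression scores share method
variance on top of any disorder factor), and measurement artefacts such
as digit preference. Consequently, passing recovery tests show that the
pipeline finds the structure the generator planted at realistic sample
sizes; they do not show that the particular published phenotypes are
correct.

## Statistical layer

The visual normality check behind the "t-test or Mann–Whitney" choice is
operationalized as Shapiro–Wilk at alpha = 0.05 in *both* groups (t-test
with pooled variance if both pass); the rule is a pure function of the
data, logged per variable, and can be forced either way for calibration
studies. Nominal comparisons use the chi-squared test without continuity
correction when all expected counts are at least 5, Fisher's exact test
otherwise. Spearman correlations are tie-corrected, over pairwise-complete
observations within the already list-wise-filtered sample. No
multiple-testing adjustment is applied by default (raw p-values are
reported); a Benjamini–Hochberg column is available.

Calibration is verified by simulation: under route-appropriate nulls the
p-values of the t, Mann–Whitney and chi-squared routes are
Kolmogorov–Smirnov-uniform, and the Mann–Whitney approximation is checked
against full permutation enumeration at small n. The Fisher route is
calibrated on sparse r x c tables (a rare nominal level forcing expected
counts below 5), where the exact test's support is rich; on tiny 2x2
tables exact-test p-values are discrete and conservative *by
construction* — there, validity means `P(p <= alpha) <= alpha`, not
KS-uniformity, which no simulation design can deliver.

## Problem sizes and determinism

The shipped analyses use the published strata sizes (164 women, 92 men;
about 50 modalities over 18 active variables), where a full stratum
pipeline runs in well under a second. Recovery properties are evaluated
over 20 seeded replicates per preset; oracle cross-checks use 50–100
random instances (clustering oracles at n <= 12, MCA references at
n <= 50, Q <= 4); calibration checks use 500 null replicates per route.
Every stochastic step is seeded: the generator from its config, k-means
from its own fixed seed, so a config determines its outputs byte for
byte.

## Known limitations

* Rare modalities get principal coordinates inflated by `1/sqrt(mass)`;
  with the fixed HADS cut-offs and men's depression distribution, the
  `hads_depression=high` modality (~5–7% of men) is occasionally extreme
  enough that Ward or k-means at k = 3 isolate it (with
  `hads_anxiety=high`) in its own cluster, emptying the three-method
  intersection of those modalities in roughly one seed in ten. The
  univariate F1 partition is immune. This is a real fragility of the
  intersection rule under rare extreme modalities, visible in the
  recovery rates the acceptance script reports.
* The MM detector parameterizes a judgement the original analysts made
  visually; its defaults (bandwidth, peak/valley thresholds) are
  documented but necessarily conventional.
* Adjusted inertia shares on the synthetic presets are higher than is
  typical of real survey data because a single latent factor carries all
  the association; raw shares are always reported alongside.
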