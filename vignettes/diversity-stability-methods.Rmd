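---
title: "Methods: diversity–population stability analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity–population stability analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divstab)
```

## The question and the quantities

Whether species diversity stabilizes or destabilizes populations in plant
communities depends partly on measurement choices. Two diversity metrics and
two stability aggregations span the space of common practice:

* **average richness** — the mean number of species present per sampling
  year; **cumulative richness** — the number of distinct species ever
  recorded in the plot; their ratio is **temporal turnover**, a
  multiplicative temporal beta diversity that is 1 exactly when no recorded
  species is ever absent and grows with transient occupancy.
* **UPCV**, the unweighted mean of the retained species' temporal CVs
  (σᵢ/μᵢ), which weights a rare species as much as a dominant one; and
  **WPCV**, the mean CV weighted by relative mean abundance pᵢ, which is
  dominated by abundant species. Stability is the inverse notion of these
  CVs.

Because species with many absence years have erratic CVs, a plot-level
occurrence filter precedes the stability metrics: a species must be present
in at least 30% of the sampled years (so at least 3 of 10). The 10% and 20%
settings exist to show robustness to that choice. Richness and turnover are
computed on the *unfiltered* data by default: the filter exists to stabilize
CV estimates, and filtering richness would suppress exactly the turnover
signal the analysis is about. A switch (`richness_filtered = TRUE`) supports
the other convention, since either is defensible.

Further conventions, fixed so that independent re-implementations agree to
machine precision:

* absence years count as abundance 0 in μᵢ, σᵢ and the detrended variance
  for retained species — their zeros are real fluctuations, and the filter
  has already removed zero-dominated series;
* σᵢ is the sample SD with the n−1 denominator;
* pᵢ normalizes over retained species only, making WPCV a convex
  combination of the CVs actually computed (both UPCV and WPCV are bounded
  by the retained species' min and max CV);
* the single most abundant species is **dominant** (ties break to the
  lexicographically smallest species identifier, so the labeling is
  order-independent); of the rest, relative abundance < 5% is **rare**,
  otherwise **subordinate**. A dominant whose share happens to fall below
  5% stays dominant: the rules apply in that order.

### Detrending

Directional abundance change inflates the plain CV. The detrended variant
replaces the sample variance with the three-term local variance

$$\mathrm{TTLV} = \frac{\sum_{t=2}^{n-1} (x_{t-1} - 2x_t + x_{t+1})^2}{6(n-2)},$$

the mean squared second difference scaled so that it is exactly zero for any
affine series and unbiased for the innovation variance of iid noise around a
linear trend (E[(x − 2y + z)²] = 6σ² for iid x, y, z with variance σ²). The
cited literature for this detrending does not pin the normalization
constant; 6(n−2) is this package's stated convention, chosen for
unbiasedness, and the tests assert it explicitly. The detrended CV is
√TTLV/μᵢ and needs at least 3 years.

## Per-dataset correlations

Within each dataset, each diversity metric is correlated with each
stability-side metric across plots, after ln-transforming both (the log base
cannot matter — Pearson r is invariant to affine maps — but natural logs
match the convention of reporting "ln-transformed" variables). Plots where
either metric is undefined or non-positive are dropped *pairwise per metric
pair*, not dataset-wide, which maximizes usable data and naturally yields
different dataset counts per pair. Datasets with fewer than 5 usable plots,
or no variation in either log metric, are excluded, with reasons logged.

For CV metrics the reported r is the negated raw correlation, so a positive
reported r always means diversity → stability; group population-size metrics
keep their raw sign. Effect sizes for pooling are Fisher's z = atanh(r) with
sampling variance 1/(n−3); a correlation of exactly ±1 (possible in
degenerate synthetic fixtures) is clamped to ±0.999999 with a warning rather
than discarded. Significance is the two-sided t-test with n−2 df at α =
0.05, unadjusted — no multiplicity correction is applied anywhere in this
analysis, matching common practice for per-dataset descriptive histograms.

## Cross-dataset synthesis

Two routes, both REML:

1. **Mixed model**: `r ~ diversity_metric × stability_metric +
   (1 | dataset)`, fitted on r itself. The metric interaction is tested with
   Satterthwaite denominator degrees of freedom (typically fractional), and
   per-combination estimated marginal means get Satterthwaite-t 95%
   intervals. REML is the conventional choice for unbiased variance
   components; fitting on r keeps the response on the scale the histograms
   display.
2. **Random-effects meta-regression** per metric combination on the Fisher-z
   scale: between-dataset variance τ² is REML-estimated (non-negative by
   construction), studies weighted by 1/(vᵢ + τ²), and the pooled mean
   back-transformed with tanh.

The two routes answer the same question on different scales and should
agree; the test suite asserts that their per-combination pooled estimates
differ by less than 0.05 on every synthetic collection it builds. That bound
is this package's chosen acceptance tolerance for "similar", not an external
constant.

Driver regressions model the per-dataset r for each core combination as OLS
on abundance-metric type (cover as reference), ln plot size, ln duration,
management coverage, mean average richness, and the first two principal
components of the dataset-level climate variables (correlation-matrix PCA;
a constant climate variable is an error naming the variable). Variance
inflation factors are reported per predictor — the screening convention is
that values below 2 indicate no problematic collinearity — and a
rank-deficient design is an error naming the aliased columns. Which climate
variables enter the PCA is the caller's choice; the generator supplies four
correlated synthetic ones so the step has structure to find.

The subgroup comparison regresses, across datasets, the r values obtained
with an overall stability metric on those obtained with a group-level metric
(unweighted vs rare-group stability; weighted vs dominant-species
stability), reporting R². In simulated collections the unweighted–rare
R² is high (rare species dominate the unweighted mean by count), the
weighted–dominant R² moderate.

## The synthetic generator

`simulate_collection()` emulates a multi-site collection of permanent
vegetation plots. Per species with target mean μ: a latent standard-normal
AR(1) series with lag-1 correlation φ is scaled to mean μ and SD √(a·μᵇ)
(Taylor's power law), a linear trend with slope ~ Normal(0, trend_sd) is
added (centred mid-series), and values below the detection limit are
recorded as 0. This is the simplest mechanism that jointly yields Taylor
scaling, temporal autocorrelation, and occupancy–abundance coupling: low-μ
species fall below detection more often, so they are simultaneously the
less abundant, less stable, and more transient species — the mechanism that
makes temporal turnover anti-correlate with unweighted stability.

Random streams are hierarchical (collection seed → dataset stream → plot
stream, via a deterministic integer derivation), so enlarging a collection
never perturbs already-generated plots, and identical configurations give
identical tables.

Default study conditions, chosen once as a realistic scaled-down collection
and not revisited: 50 datasets × 30 plots × 15 years; 40-species pools with
lognormal(meanlog 1, sdlog 1.2) mean abundances (a strong dominance
hierarchy, dominant share typically 20–60%); Taylor a = 0.5 and b = 1.7 —
below 2, the empirically prevalent regime, so dominants are intrinsically
more stable; AR(1) φ = 0.3 (weak interannual persistence); detection limit
0.2 abundance units (a fraction of a percent-cover unit); trend SD 0.02 per
year; a plot-level lognormal productivity factor (sdlog 0.4) and a
species-by-plot lognormal deviation (sdlog 0.5, microhabitat response) that
create between-plot variation in richness, stability, and composition.
Dataset covariates draw the abundance-metric label (cover 60%, biomass 25%,
frequency 15%), lognormal plot sizes, uniform management coverage, and four
climate variables loading on two latent factors.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: species interactions are absent (fluctuations are
independent across species given their means), sampling error in abundance
estimation is not modeled separately from process noise, plot counts and
durations are homogeneous within a collection rather than spanning 6–99
years, and abundance units are not tied to real cover/biomass scales.
Simulated diversity–stability correlations are therefore much stronger
(|r| often 0.5–0.9) than the weak correlations typical of real collections;
the analysis pipeline is validated on the *structure* (signs, orderings,
recovery of planted effects), not on matching empirical effect sizes. One
visible artifact: with a fixed detection limit, cumulative richness can
saturate at the same integer in every plot of a dataset, which triggers the
no-variation exclusion more often than in real data.

## Numerical and degenerate-input choices

* All-zero species series and never-occupied plots are errors, not NaNs.
* A plot with no species surviving the filter is excluded from stability
  outputs but still reported for richness.
* Empty dominance groups yield NA group metrics, dropped pairwise by the
  correlation stage.
* `|r| = 1` → clamp to ±0.999999 before atanh (warning).
* The mixed model refuses designs where a metric combination is entirely
  absent (degeneracy error naming the combination) rather than silently
  dropping a contrast.
* Problem sizes in the test suite: oracle equivalence uses 1000 random
  small plots (≤ 6 species, ≤ 8 years) against loop-based brute-force
  re-implementations at 1e-10 relative tolerance; Taylor-law checks use 500
  species × 200 years; recovery exercises use 100–200 datasets; end-to-end
  checks run the default 50 × 30 × 15 collection.

## Worked pipeline run

```{r example, eval = FALSE}
sim <- simulate_collection(sim_config(n_datasets = 12, plots_per_dataset = 15,
                                      years_per_plot = 12, pool_size = 30,
                                      seed = 101))
fit <- divstab(sim$records, sim$covariates)
summary(fit)
plot(fit)
```

The summary reports the metric-interaction F with its fractional
denominator df, per-combination pooled correlations from both synthesis
routes, heterogeneity τ², and the subgroup R² values; `run_pipeline()`
writes the same content to disk as CSV + JSON + text, stamped with a
configuration hash and seed.

## Known limitations

* Community-level (aggregate) stability and synchrony decompositions are
  out of scope; the unit of analysis is the population.
* The generator's covariates are synthetic; driver-regression results on
  simulated data validate the machinery, not ecological driver claims.
* Kenward–Roger degrees of freedom are not offered; Satterthwaite only.
* With very short series (3–4 years) the occurrence filter quantizes
  coarsely (a 30% threshold on 3 years keeps single-occurrence species),
  so stability estimates at the minimum duration are noisy by construction.
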