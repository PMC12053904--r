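---
title: "Flagging disturbance anomalies against a seasonal baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging disturbance anomalies against a seasonal baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spillwatch)
```

## The problem

A coastal microbial observatory that has sampled the same site for a
decade holds an implicit null model: every genus and gene family has a
typical seasonal rhythm and a typical amount of year-to-year drift. When
an acute disturbance hits — an oil spill, an unusual storm — the question
is not "did abundances change?" (they always do, every autumn) but "did
they move outside what ten years of natural fluctuation can produce at
this time of year?". `spillwatch` operationalizes that question.

## The baseline model and its assumptions

For each feature the centered and scaled abundance is regressed on
categorical **year** and categorical **month**, additively, with
sum-to-zero effect coding:

$$z_{sf} = \mu_f + \alpha_{f,\mathrm{year}(s)} + \beta_{f,\mathrm{month}(s)} + e_{sf}.$$

The choices embedded here matter:

* **Categorical months, not harmonics.** Seasonality is allowed to be any
  shape; nothing forces smoothness. The cost is 11 month parameters
  instead of 2–4, acceptable with a decade of samples.
* **Additive, no year×month interaction.** An interaction term would have
  one parameter per observed cell and would absorb exactly the
  disturbance signal we want to detect. Residuals therefore contain both
  noise and any year-specific seasonal deviation — which is the point.
* **Sum-to-zero coding** makes year and month effects interpretable as
  deviations from the grand mean; residuals are identical under any
  full-rank coding, so this choice affects reporting only. Year effects
  and month effects each sum to zero.
* **Joint fit over all samples** (baseline and post-disturbance) is the
  default `fit_scope = "all"`. Post-period samples then have well-defined
  year effects, at the price of the disturbance slightly contaminating its
  own year's effect (conservative: it shrinks residuals toward normal).
  `fit_scope = "baseline_only"` fits on baseline samples only and predicts
  the rest; post samples from unseen years get a zero year effect, with a
  logged caveat. The interval is always computed from baseline-period
  residuals only.

**Type II ANOVA** partitions variability per feature:
`SS_year = RSS(month-only) − RSS(full)` and symmetrically for month, with
F tests against the full model's residual mean square. On balanced designs
this coincides with sequential sums of squares in either order; on the
irregular sampling of real field campaigns it is order-invariant, which is
why it is used. All features share one design matrix, so the entire table
is fit with a single QR decomposition.

## The interval and the flag

Per feature, baseline residuals with signed value greater than the
exclusion threshold (default 4, in z units) are removed, and the empirical
2.5% and 97.5% quantiles (type-7 interpolation) of the retained residuals
form the 95% interval. Decisions behind this:

* **Empirical quantiles over mean ± 1.96 sd.** Residuals of compositional
  abundance data are routinely skewed and heavy-tailed; order statistics
  do not assume a shape. `interval_kind = "normal"` provides the
  parametric alternative.
* **The exclusion rule is signed** (`residual > 4`), trims only the upper
  tail, applies only to baseline-period residuals, and by default affects
  both the exported density panels and the interval itself — excluding
  extreme past excursions from the interval is the conservative reading
  (it narrows the envelope and can only add flags); a toggle restricts
  exclusion to the density export.
* **Strict inequality at the bounds**: a residual exactly on a bound is
  `normal`. With continuous data ties have measure zero; the convention
  only pins the degenerate case.
* Intervals from fewer than 20 retained residuals warn
  (`[spillwatch:interval-unstable]`); fewer than 2 is an error.

KO-level residuals can be aggregated to the per-module **median** by
sampling date (`module_median_residuals()`; even counts use the central
pair's mean), and the same interval/flag machinery applies to the module
table. `monthly_anomaly_panel()` groups baseline residuals by calendar
month with the flagged post-period points attached — the tabular form of a
ridgeline figure.

## Surrounding analyses

Alpha diversity uses natural logs throughout, forced by defining evenness
as `J = H / ln S`; `J` is `NA` when fewer than two features are detected,
and richness counts abundances strictly above a configurable threshold
(default 0 — RPKM is continuous, so presence is any nonzero value).
PCA is the eigendecomposition of the covariance of the z-scored table,
with each component's sign fixed so its largest-magnitude loading is
positive (PC1 time series are otherwise sign-ambiguous between runs).
PERMANOVA permutes labels freely, counts ties as exceedances, and uses the
`(1 + count)/(n + 1)` estimator, so the smallest attainable p is exactly
`1/(n_permutations + 1)`; an exhaustive mode enumerates all label orders
for small n. Nearest-neighbor dissimilarity is the Euclidean distance to
the *temporally preceding* sample — the package reads "nearest neighbor"
as adjacency in time, since the series is the object of interest.
IndVal uses the group-size-corrected specificity (per-stage means, not
sums); allowed stage combinations default to all singletons plus the union
of the post-disturbance stages, the minimal set that supports selecting
features tied to one post stage or to all of them; p-values are raw by
default (BH optional).

## What the simulator emulates — and what it does not

`sim_config()` defines a lognormal community: per taxon, log10 abundance is
a base level plus i.i.d. Gaussian year effects, i.i.d. Gaussian month
effects, an optional disturbance term, and Gaussian noise. Defaults are
chosen to look like a decade-scale coastal survey: 11 years from 2011
(the last year is the post period), two samples per month, seasonal sd
0.3 > interannual sd 0.15 > noise reference 0.2 (log10 units), and a
7-day disturbance lag reflecting the week-scale delay between exposure
and community response in such events. Month effects are drawn i.i.d.
per taxon rather than as smooth harmonics because the detector treats
months categorically — categorical truth gives clean recovery tests;
disturbances are role-targeted pulses (negative on susceptible taxa,
positive on responders) with configurable window and lag. KO profiles are
sparse nonnegative mixtures of taxa with multiplicative noise, so
functional anomalies inherit taxonomic disturbances.

In the log domain the generator matches the detector's linear model
exactly; on the raw scale (as the field pipeline runs, z-scoring RPKM
directly) the model is only approximately specified. The tests exercise
both regimes. The simulator does **not** emulate: compositional coupling
from sequencing depth, autocorrelated noise, taxon-taxon interactions,
irregular gaps, or count-level sampling noise (an optional count mode can
be layered via `rpkm_normalize()`). Passing tests therefore demonstrate
correctness of the statistics and calibration under the stated model, not
robustness to every pathology of real metagenome series.

## Numerical and testing choices

* Problem sizes in the test suite are desk-scale by design: calibration
  suites use 11 simulated years at 4–8 samples per month and 25–60 taxa
  (≥ 2000 feature × sample evaluations for coverage checks), and the
  end-to-end run uses 528 samples × 300 taxa × 2000 KOs with 999
  permutations.
* The null-coverage check compares the held-out-year flag rate to an exact
  binomial 99% band around 0.05; with ~1000 baseline residuals per feature
  the empirical interval's finite-sample undercoverage (~0.1–0.3
  percentage points) is well inside the band.
* Permutation-null uniformity is checked by KS test on 1000 simulated
  datasets; for PERMANOVA this uses 12 points in two groups of six,
  because at n = 6 the permutation lattice has only 10 distinct statistic
  values and a continuous-uniform comparison is meaningless, while the
  exhaustive-enumeration oracle is checked at n = 6 where enumeration is
  exact.
* Ties in top-k ranking break lexicographically; IndVal best-combination
  ties keep the first combination in the fixed enumeration order
  (singletons sorted, then the post union) — both purely for determinism.
* Degenerate inputs fail loudly with stable, greppable message prefixes
  (`[spillwatch:<code>]`): all-zero samples, single-level factors,
  aliased designs, duplicate dates without a tie break, empty modules.

## Known limitations

* The residuals of an additive year+month model are exchangeable only
  approximately; serial autocorrelation (storm weeks, upwelling runs)
  inflates the effective false-positive rate slightly — GLS/ARIMA
  alternatives are out of scope.
* Unseen years under `baseline_only` fitting receive a zero year effect;
  with strong interannual drift this biases post-period residuals.
* The PERMANOVA is one-way; no strata or nested designs.
* The responder panel shipped in `inst/extdata/` lists only the curated
  main-text genera; site-specific panels should be supplied as data.
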