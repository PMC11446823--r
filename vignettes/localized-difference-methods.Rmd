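---
title: "Localized difference between national predictions and mobile monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized difference between national predictions and mobile monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localdiff)
```

# The problem

National land-use-regression (LUR) products predict NO2 and ultrafine
particle (UFP) concentrations at census block-group resolution across the
whole country. Within a single city those predictions can miss hyperlocal
peaks (< 100 m) and neighborhood-scale gradients, because a national linear
model is fit to generalize over a wide domain and regresses toward central
tendencies. When such predictions are used for within-city epidemiology or
environmental-justice assessment, the resulting exposure misclassification
can be structured: larger near certain pollution sources, and different
across demographic groups.

`localdiff` quantifies this structure. Its unit of analysis is the
**localized difference** per 0.01 km^2 grid cell `i`:

```
LD_i = MM_i - LUR_i
```

where `MM_i` is a mobile-monitoring estimate of the long-term concentration
in the cell and `LUR_i` is the national prediction resampled to the cell.
Positive LD means the national model underpredicts locally. LD is a
*difference*, not an *error*: mobile monitoring is itself an uncertain,
daytime-weekday-only estimate, but it is independent of the national model
and resolves local peaks.

# From 1 Hz points to cell estimates

Mobile monitoring yields 1 Hz measurements along roads. The gridding
protocol (`grid_concentration_field()`):

1. assign each point to a half-open 100 m x 100 m cell
   (`[x0, x0+100) x [y0, y0+100)`, so boundary points have a unique cell);
2. within a cell, split the time-ordered points into **drive passes** —
   maximal runs whose consecutive gaps do not exceed `gap_threshold_s`;
3. average points within a pass (the pass mean), then take the **median of
   pass means** as the cell estimate.

The median weights each visit evenly regardless of dwell time and is robust
to a single anomalous pass. Two choices deserve attention:

* `gap_threshold_s = 60` by default. The pass-separation rule is a protocol
  parameter with no canonical value; 60 s exceeds within-visit dwell at
  urban driving speeds yet splits distinct loop visits. Because estimates
  depend on it, it is surfaced in every interface rather than hard-coded.
* Pass membership is per cell: a vehicle weaving along a cell boundary
  creates interleaved passes in the two cells, each isolated from that
  cell's own stream. Single-pass cells are retained (identifiable via
  `n_passes`); no minimum-visit filter is imposed.

# Harmonization

Block-group inputs are brought onto the grid by area weighting
(`areal_resample()`): a cell's prediction is the overlap-area-weighted
average of intersecting block groups. Population is handled differently
(`allocate_population()`): counts are allocated *proportionally to overlap
area*, `pop_g * A(g ∩ cell) / A(g)`, per racial/ethnic group, and cell
shares are recomputed from allocated counts. Averaging population counts
across unequal-area donors would not conserve people; proportional
allocation conserves every group's total exactly, which the tests assert to
1e-9 relative. Geometry is computed in projected meters with exact convex
clipping. Sliver intersections below 1 m^2 are discarded when averaging
*values* (robustness against degenerate weights), but never when allocating
*counts*, where dropping even a sliver's worth of people would break
conservation.

# Known-local-source features

Twenty-one predictors describe pollution-related infrastructure around each
cell: seven source types (residential, arterial, highway and on-ramp roads;
food service; gas stations; industrial land) at three distances (50, 150,
300 m) from the cell edge. The buffer is the Euclidean dilation of the cell
square (rounded corners), with closed-form area
`(s + 2d)^2 - (4 - pi) d^2`. Road classes are measured as km of road per
km^2 of buffer, commercial points as locations per km^2, industrial land as
the share of buffered area (overlapping parcels unioned first).

The density denominator is the *buffered* area, not the fixed cell area:
"within d of the cell edge" names the numerator's support, and using the
matching area keeps densities comparable across distances. Line lengths
within the dilation are computed exactly (parameter-interval intersection
with the union of two slabs and four corner disks); the industrial share is
a ratio of areas measured on one polygonal buffer (24 segments per corner,
relative area error < 1e-4), so a parcel covering the whole buffer scores
exactly 1. Industrial parcels are assumed convex.

Many of these features are zero over most of the domain. The feature matrix
reports each column's zero fraction, because sparsity determines the shape
of the downstream inference: for a mostly absent source, the meaningful
quantity is the presence/absence step of the partial-dependence curve, and
the evaluation grid therefore always includes the exact value 0 for
zero-inflated features.

# The BART model

LD is regressed on the 21 features with Bayesian Additive Regression Trees:
`y = sum_{t=1}^m g(x; T_t, M_t) + e`, `e ~ N(0, sigma^2)`. The sampler is
the standard Bayesian backfitting MCMC:

* response internally rescaled to [-0.5, 0.5]; leaf means have prior
  `N(0, sigma_mu^2)` with `sigma_mu = 0.5 / (k sqrt(m))`;
* a node at depth `d` splits with prior probability `alpha (1+d)^-beta`;
* `sigma^2 ~ nu lambda / chi^2_nu`, `lambda` set so the prior puts
  probability `q` below the least-squares residual variance;
* per iteration each tree receives a grow, prune or change proposal
  (probabilities 0.28 / 0.28 / 0.44), accepted by Metropolis–Hastings
  against the residual of the other trees under the conjugate marginal
  likelihood; leaf means and then `sigma^2` are drawn from their conjugate
  conditionals.

Defaults are `m = 50`, `k = 2`, `nu = 3`, `q = 0.9`, `alpha = 0.95`,
`beta = 2`, 250 burn-in and 1000 retained draws — the standard sum-of-trees
prior, chosen for comparability with common BART implementations rather
than tuned to any data. Split rules propose a uniformly drawn variable
among those with at least two distinct values at the node and a uniformly
drawn observed value of it (excluding the node minimum), with the strict
`< left / >= right` rule; both children are therefore always non-empty, and
the rule prior equals the proposal distribution, so rule probabilities
cancel from every acceptance ratio. Because constant columns are never
eligible, adding all-constant predictors to a model consumes no randomness
and reproduces the smaller model exactly under the same seed — a property
the tests assert.

Degenerate inputs: a constant response cannot inform a split, so the fit is
flagged and returns an intercept-only posterior with pseudo-R^2 = 0.

## Inference products

* **Partial dependence** (`partial_dependence()`): for evaluation value
  `v`, substitute `x_j = v` into *all* training rows, average each retained
  draw's predictions over rows, and summarize across draws (mean and
  2.5/97.5 percentiles). The x-axis is reported both in feature units and
  as empirical quantiles. The implementation short-circuits trees that
  never split on `x_j`; a brute-force loop over rows and draws is kept in
  the test suite as the oracle, and agreement is asserted to 1e-9.
* **Presence/absence step** (`pdp_step()`): the posterior contrast
  PDP(v) - PDP(0), computed per draw so its credible interval reflects
  joint uncertainty.
* **Variable-inclusion proportions** (`variable_inclusion_proportions()`):
  per draw, the fraction of all split rules using each feature (a splitless
  draw contributes the uniform 1/p), averaged over draws; proportions sum
  to one and `top_vip()` returns the leading eight by default.
* **Fit summaries**: pseudo-R^2 `= 1 - SSE/SST` from posterior-mean
  in-sample predictions, and NRMSE `= RMSE / |mean(y)|` (the absolute value
  matters because mean LD can be negative, as for NO2).

# Demographic analyses

Two complementary views of whether LD accrues differentially by
race/ethnicity:

* **Population-weighted LD distributions**
  (`population_weighted_quantiles()`): quartiles of LD weighted by each
  group's allocated population per cell. The weighted quantile is the
  left-continuous inverse of the weighted ECDF with the midpoint convention
  at exact crossings; with integer weights it equals the ordinary type-2
  quantile of the weight-expanded sample, which is the test oracle.
  Allocated *counts* (not shares) are the weights.
* **Model A / Model B** (`fit_model_a()`, `fit_model_b()`): BART fits of LD
  on (Pop, five shares) and on (Pop, five shares, 21 KLS features). The
  change in a demographic PDP from A to B is summarized by
  `pdp_attenuation()` as the ratio of curve amplitudes over a *frozen*
  evaluation grid (Model B reuses Model A's grid); a ratio below one means
  source densities explain part of the demographic relationship, a ratio
  near one means they do not.

# The synthetic-scene generator

Real campaign data are large and access-controlled; the generator
(`generate_scene()`) builds a miniature domain with every statistical
feature the analysis relies on, plus known ground truth, so each stage is
testable by parameter recovery:

* several discontiguous square neighborhoods tiled by 100 m cells;
* gridded road networks by class (defaults: residential every 200 m,
  arterial every 600 m, one horizontal highway per 1600 m with on-ramp
  stubs at alternate arterial crossings), so highways are sparse;
* food-service and gas-station points placed near arterials (sources
  co-locate with traffic, enabling confounding experiments), rectangular
  industrial parcels;
* ground truth = background + exponential source kernels
  `strength * exp(-d / L)`. Decay lengths default to 160-250 m, inside
  `250/ln 10` to `250/ln 2` (109-361 m), the range for which the excess
  falls two- to ten-fold between 50 m and 300 m of a source — the
  characteristic near-source behavior of NO2 and UFP;
* 1 Hz traces drive every road `n_drive_passes_per_cell` times on weekday
  daytimes (08:00-18:00), each pass on a separate day, with mean-1
  lognormal multiplicative noise (`exp(N(0, sd) - sd^2/2)`), so pass means
  are unbiased for cell truth and the median-of-means estimator is
  consistent. The noise sd (default 0.35 for UFP, 0.25 for NO2 on the log
  scale) is a free parameter: 1 Hz temporal variability has no single
  canonical value;
* block groups are random rectangular partitions of each neighborhood, cut
  at positions not aligned to the monitoring grid, so areal weighting is
  genuinely exercised;
* the "national model" is the fitted value of a linear regression of
  block-group-mean truth on coarse covariates (road length, population)
  plus an additive bias per pollutant (defaults: -12 for UFP, emulating
  systematic underprediction; +0.9 ppb for NO2, slight overprediction). As
  a linear smoother of block-group means it cannot represent within-group
  extremes — exactly the deficiency LD measures;
* demographics: each block group's mean white share is logit-normal
  (sd 0.6) around 0.42, tilted by standardized local source density with
  strength `demo_source_corr` (negative values place people of color near
  sources); the relative mix of the non-white remainder varies
  independently across block groups (Dirichlet(5 x base mix)); realized
  shares are Dirichlet(40 x mean). The two independent variance components
  matter: real urban domains have Hispanic-, Asian- or Black-predominant
  neighborhoods, not one fixed minority mix, and without that independent
  variation the five compositional shares are so collinear that no
  regression method can attribute a share effect to the correct share.

What the generator does **not** emulate: street-network routing, meteorology
and temporal covariance of concentrations, instrument drift or lag,
on-road versus ambient offsets, and the internal structure of real national
models. Passing recovery tests therefore demonstrates that the estimators
are correct under the stated data-generating assumptions, not that any
real-world dataset satisfies those assumptions.

# Numerical and testing choices

* All geometry is planar, in projected meters; there is no geodesy. The
  geometry layer is exact for the operations used (convex clipping,
  shoelace areas, segment-in-dilation lengths); the only approximation is
  the polygonal buffer boundary for industrial areas (relative error
  < 1e-4).
* Determinism: one seed drives scene generation (with derived sub-seeds per
  layer), the MCMC uses R's RNG, and the pipeline records seeds, config and
  file hashes in per-stage manifests; reruns with unchanged inputs are
  no-ops, and tampered intermediates are refused.
* Recovery-test problem sizes: the source-effect check uses four 1.6 km
  neighborhoods (1024 cells) with a 10-unit presence effect and noise sd 2;
  the demographic checks use twelve (direct effect) and six (confounded)
  1 km neighborhoods with noise sd 0.75, a signal-to-noise ratio comparable
  to a model explaining roughly two-thirds of LD variance. Chains in tests
  use 100 burn-in / 150 retained draws, enough for these effect sizes;
  production defaults are longer.
* The Model A recovery check compares the white-share PDP amplitude with
  the known coefficient times the 5th-95th percentile spread. Some
  shortfall is expected: compositional shares remain negatively correlated
  and tree ensembles shrink extremes, so the tolerance (25%) is a
  recovery band, not a claim of unbiasedness.

# Limitations

* Industrial-parcel union assumes convex parcels; concave outlines must be
  pre-split.
* Polygons with holes are not supported by the GeoJSON readers (outer rings
  are used, with a warning).
* The sampler is single-chain; convergence diagnostics across chains are
  out of scope, and posterior summaries inherit single-chain Monte Carlo
  error.
* Mobile-monitoring estimates are treated as the benchmark; LD confounds
  national-model error with monitoring uncertainty by construction, which
  is why it is called a difference and not an error.
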