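---
title: "Interannual chlorophyll-temperature associations in large lakes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interannual chlorophyll-temperature associations in large lakes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakecor)
```

## The estimation problem

Satellite archives provide long, gappy records of lake surface temperature
(LST, °C) and surface chlorophyll-a (chl-a, mg m⁻³, a phytoplankton biomass
proxy) on a grid. The scientific question is *interannual*: in years when a
lake runs warm, does it also run green? Seasonal covariation (both
temperature and biomass cycle over the year) must not contaminate the
answer, and neither should the satellite's sampling pattern, because clouds
and ice preferentially hide particular seasons and places.

`lakecor` estimates, for each lake, a spatially and seasonally balanced
mean interannual rank correlation between chl-a and LST, and then asks
which lake attributes explain the variation of that quantity across lakes.

## Stage 1: reduction and the correlation field

Native grids are median-filtered and subset to 0.1° cells and 5-day bins
(`spatial_median_subset()`, `temporal_median_subset()`). Cells are tiled
half-open, anchored at integer multiples of 0.1°, and reported at cell
centres; 5-day bins are anchored at January 1 of each calendar year (bin
index `floor((doy - 1)/5) + 1`, the last bin absorbing day 366) so that the
same bin index refers to the same part of the season in every year — the
alignment the interannual analysis needs. Even-count medians use the mean
of the two central order statistics.

Coincident pairs (both variables present in a cell-bin-year,
`match_coincident()`) are grouped into subdivisions by (pixel, day-of-year
bin): each subdivision holds at most one pair per year, so correlation
*across* its entries is correlation *across years* at a fixed place and
season. Subdivisions with at least 8 coincident pairs get a Kendall rank
correlation (`kendall_tau()`); smaller ones are counted and dropped. We use
tau-b (tie-corrected) because median filtering can produce ties, with a
two-sided p-value from the exact null distribution for n ≤ 10 without ties
and from the tie-corrected normal approximation otherwise. Subdivisions
whose correlation is undefined (a completely tied variable) are excluded
rather than scored zero, which would deflate lake-wide magnitudes.

## Stage 2: balancing away the sampling bias

The observed correlations r_i are not evenly distributed over space and
season, so their plain mean is biased toward the best-observed strata. The
debiasing estimator (`fit_lake_surface()`, `balanced_ensemble()`):

1. fits a boosted regression tree of r_i on latitude, longitude and
   day-of-year stratum (interaction depth 3, one split per predictor per
   the complexity rule), on at most 10,000 records (a seeded uniform
   subsample above that);
2. draws n ensemble members by sampling an observed pixel and an observed
   stratum independently and uniformly **with** replacement from the unique
   observed lists, predicting the modelled correlation there;
3. adds to each member a residual drawn **without** replacement from the
   fit's residual pool (the pool is a permutation, consumed exactly once),
   restoring the dispersion the model removed;
4. reports r_lake as the mean of the members and tests the members against
   zero with a two-sided Wilcoxon signed-rank test (exact by convolution
   over doubled midranks for n ≤ 25, tie-corrected normal approximation
   with continuity correction above); Benjamini–Hochberg adjustment is
   applied across lakes.

Uniform resampling over the observed unique lists is what removes the
bias: every observed place and season contributes equally, regardless of
how often it was seen. Sampling with replacement is forced by n typically
exceeding the number of unique combinations; pixels are drawn as observed
(lat, lon) *pairs* so the surface is never queried at never-observed
off-lake locations. The Wilcoxon test is applied to the ensemble members —
the same quantities averaged into r_lake — rather than to the raw r_i's;
the members are not independent (they share one fitted surface), so the
per-lake test is approximate and the null-calibration test asserts only a
soft bound (observed false-positive rate ≲ 10% pre-adjustment).

## The boosting engine

No boosting implementation is available in the package's dependency
environment, so the engine is built in (C++ via Rcpp): stagewise
least-squares gradient boosting with best-first trees, bag fraction 0.5,
10-fold cross-validation for tree-count selection, per-split improvement
accounting for relative influence, and empirical-marginalisation partial
dependence. Design points worth knowing:

* **Weights.** Observation weights scale the loss, the split gains, the
  leaf values and the influence accounting; node size limits are measured
  in weight, so duplicating an observation and doubling its weight are
  *exactly* equivalent.
* **Missing values.** At each split the missing group is sent left or
  right, whichever reduces loss more; the direction is stored, so
  prediction handles missing (and unseen categorical) values without
  dropping rows.
* **Determinism.** A self-contained xorshift generator drives bagging and
  fold assignment; identical seeds give bit-identical models on any
  platform.
* **Tuning.** `tune_learning_rate()` walks the descending grid 0.1, 0.05,
  0.01, 0.005, ..., 1e-4 and accepts the first rate whose cross-validated
  tree count lies in [1,000, 10,000]. The CV loop early-stops `patience`
  (500) trees after the last improvement, but never before 1,000 trees, so
  the acceptance decision always sees the window's lower edge.
* **Flat curves.** A lake whose correlation surface is genuinely
  homogeneous gives a CV curve that rises from the first iteration at
  every learning rate — the protocol's demand for ≥ 1,000 trees can then
  never be met by an argmin, even though the lake has abundant data and an
  obvious answer (the constant surface). We therefore accept a rate when
  the CV error at 1,000 trees is within `flat_tolerance` (default 1%,
  relative) of the curve minimum: the fit at the window's edge is then
  statistically indistinguishable from the optimum, and elimination is
  reserved for genuine data insufficiency (too few records to support any
  admissible fit — a model that cannot place a single split is always
  eliminated). Measured overfit rises of structured surfaces at too-high
  learning rates are 1–2 orders of magnitude above this tolerance, so the
  two regimes separate cleanly.

The 10 folds, bag fraction 0.5 and minimum node weight 10 are the
conventional defaults of the boosted-tree protocol this follows; the
sources state only the complexity rule, the tree-count window and the
learning-rate floor.

## Stage 3: explaining r_lake across lakes

`fit_crosslake()` models r_lake on eight attributes — elevation, latitude,
surface area, perimeter, mean depth, salinity class (fresh/saline),
median temperature, median chl-a — with interaction depth 8, each lake
weighted by `1 − p` from its Wilcoxon test so weakly determined lakes count
less. Attributes may be partially missing; rows are never dropped.
`medianchl_effect()` isolates the median chl-a effect as a partial
dependence curve over a log-spaced grid spanning the observed range
(reported with log10-x and asinh-y display transforms). Partial dependence
was chosen over residualisation schemes as the standard reading of
"removing variability attributable to the other predictors" for tree
ensembles. Predictors enter untransformed: trees are invariant to monotone
transforms.

## The synthetic world

`generate_lake_catalog()` / `simulate_observations()` stand in for the
satellite archives. Within each (pixel, 5-day bin) stratum, interannual
anomalies of LST and log chl-a are coupled by a Gaussian copula with
correlation ρ(pixel, bin); chl-a is lognormal around the lake median, so
positivity holds and — because Kendall's tau is invariant under monotone
transforms — the population tau of every stratum is exactly
(2/π)·arcsin(ρ). That closed form is the generator's ground truth
(`TruthTable`), and the balanced target `true_r_lake` is the unweighted
mean of the per-stratum taus. Missingness is independent Bernoulli per
cell with a configurable (pixel, bin) probability surface, which is how
seasonally biased sampling is produced; persistent cloud runs and ice
phenology are deliberately not modelled. Years are independent — real
records have some interannual autocorrelation within strata; none of the
estimators assumes otherwise, but Monte-Carlo p-value calibration on real
data will be somewhat more diffuse than in this synthetic world.

Defaults state the emulated conditions: 15 years (a 2002–2016-style span),
10×10 pixels of 0.1°, 73 five-day bins, observation probability 0.8,
seasonal LST amplitude 8 °C, interannual anomaly scales 1.5 °C and 0.6 log
units, and a log-uniform trophic gradient of median chl-a over 0.1–100
mg m⁻³. With `amplification = TRUE` the mean coupling rises linearly in
log10 median chl-a from about −0.6 to +0.6, crossing zero mid-gradient —
phytoplankton-poor lakes couple negatively and phytoplankton-rich lakes
positively, which is the qualitative cross-lake truth the pipeline should
recover. Catalog lakes additionally carry a ±0.25 seasonal modulation of ρ
(coupling strength genuinely varies over the year in real lakes); this
also means each lake's correlation surface has learnable structure, which
the per-lake tuning requires. A green synthetic run establishes that the
estimators recover a known stated world of this structure; it does not
validate the satellite retrievals themselves, radiative transfer, or
behaviour under spatially correlated cloud cover.

## Validation statistics

`sma_fit()` implements standardized major axis regression — the symmetric
line fit appropriate when both variables carry error — with slope
sign(r)·sd(y)/sd(x), and the standard F-based 95% confidence interval.
`match_nearest()` pairs in-situ samples with the nearest coincident
satellite cell (defaults: 4 km, 5 days — the cell and bin scales — with
ties broken by temporal offset then coordinates). `validation_report()`
reports SMA, Pearson correlation and median absolute error per variable,
and lake-level comparisons when at least three lakes are available. Chl-a
can be compared raw (default) or on log10; the generator's multiplicative
bias maps to a pure intercept shift on the log scale.

## Numerical choices and degenerate inputs

* Exact Kendall null distributions are built by the inversion-count
  convolution and cached per n; counts stay exactly representable in
  doubles through n = 10.
* The exact Wilcoxon distribution is built over doubled midranks, so ties
  are handled exactly; the two-sided p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`.
* Constant responses are a degenerate-fit error; completely tied
  correlation inputs return a no-result marker and are counted.
* Split ties in the tree engine break toward the lower predictor index and
  the earlier cut; gains must exceed zero to split at all.
* Seeds: every stochastic stage takes one; derived stream seeds stay below
  2³¹. Identical configuration implies byte-identical pipeline outputs.

## Known limitations

Lag structure between warming and biomass response is not modelled (only
coincident association). The per-lake significance test inherits the
dependence of ensemble members on a shared surface; its p-values are
indicative, which is why they enter the cross-lake stage as *weights*
rather than as hard filters. The engine's categorical handling splits on
level codes, exact for two-level factors (the only categorical in the
catalog schema); many-level categoricals would need subset splits.
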