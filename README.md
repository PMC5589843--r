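# lakecor

Interannual associations between lake surface chlorophyll-a and lake
surface temperature, estimated lake-wide from gapped satellite-style
grids.

## The problem

In years when a large lake runs warmer than usual, does its phytoplankton
biomass (tracked by surface chlorophyll-a, mg m⁻³) run higher or lower?
Metabolic ecology predicts *lower* — warming raises basal metabolic costs,
so fixed resources support less biomass — but trophic interactions and
nutrient dynamics can push the other way, and which effect wins appears to
depend on a lake's trophic state.

Answering this from satellite archives has two statistical obstacles.
First, both temperature and chlorophyll cycle seasonally, so raw
correlations are dominated by the annual cycle rather than by interannual
forcing. Second, clouds and ice hide particular seasons and places, so
averaging whatever was observed biases any lake-wide summary toward the
best-observed strata. `lakecor` implements a pipeline that deals with
both, for researchers in aquatic remote sensing and lake ecology:

1. **Reduction** — median filter and subset to 0.1° cells and 5-day bins;
   keep cell-bin-years where both variables are observed.
2. **Correlation field** — within every (pixel, day-of-year bin)
   *subdivision* (at most one pair per year, at least 8 years required),
   Kendall's tau-b between chl-a and LST across years:
   r_i with exact small-sample p-values.
3. **Debiasing** — a boosted regression tree of r_i on (lat, lon, season)
   plus balanced resampling: members r̂_i + e_i, with (pixel, season)
   drawn uniformly over the *observed unique lists* (with replacement) and
   residuals e_i drawn *without* replacement. The lake-wide correlation is
   r_lake = mean(r̂_i + e_i), tested against zero by an exact/approximate
   Wilcoxon signed-rank test, Benjamini–Hochberg-adjusted across lakes.
4. **Cross-lake model** — a boosted regression tree of r_lake on eight
   lake attributes, each lake weighted by 1 − p; relative influence and
   the isolated (partial-dependence) effect of median chl-a.
5. **Validation** — in-situ vs satellite comparison by standardized major
   axis regression (slope = sign(r)·sd(y)/sd(x)), Pearson correlation and
   median absolute error.

A Gaussian-copula synthetic-data module generates multi-lake grids with a
known per-stratum Kendall tau — (2/π)·arcsin(ρ) — and a known balanced
lake-wide target, so every stage is testable offline against ground truth.
The gradient-boosting engine (squared-error loss, observation weights,
missing-value routing, 10-fold cross-validated tree selection in the
[1,000, 10,000] window with learning-rate tuning down to 1e-4, relative
influence, partial dependence) is implemented in the package in C++.

See `vignettes/lakecor-methods.Rmd` for the model assumptions, tuning
rules and design decisions.

## Worked example

A lake whose coupling flips sign with season (ρ = +0.5 in summer strata,
−0.5 in winter), observed through cloud cover that oversamples summer
about 4:1 — the configuration in which a naive mean is badly biased:

```r
library(lakecor)

rho_bin <- ifelse((1:73) >= 19 & (1:73) <= 54, 0.5, -0.5)
sc <- lake_scenario(lake_id = "demo", n_pixels_lat = 3, n_pixels_lon = 3,
                    rho_by_bin = rho_bin,
                    obs_prob_by_bin = ifelse(rho_bin > 0, 0.9, 0.45),
                    seed = 101)
sim <- simulate_observations(sc)
nrow(sim$observations)
#> [1] 6669
sim$truth$true_r_lake          # balanced ground truth
#> [1] -0.00456621

field <- correlation_field(subdivide(sim$observations))
nrow(field)
#> [1] 447
mean(field$tau)                # naive mean: biased toward summer coupling
#> [1] 0.1605012

surface <- fit_lake_surface(field, seed = 202)
ensemble <- balanced_ensemble(surface, seed = 303)
summarize_lake(ensemble)
#>   lake_id      r_lake wilcoxon_p   n
#> 1    demo 0.007756952  0.5431892 447
```

The seasonally balanced truth is ≈ 0 (the two seasons cancel), yet the
naive mean of the 447 observed correlations is +0.16 because summer
dominates the sampling. The debiased estimate r_lake ≈ 0.008 recovers the
truth, and its Wilcoxon p (0.54) correctly reports no evidence of a
lake-wide association.

The whole pipeline, from synthetic catalog to cross-lake influence report,
runs with:

```r
res <- run_pipeline(pipeline_config(n_lakes = 12, seed = 42), "out/")
```

which writes every intermediate table (catalog, observations, correlation
field, lake summaries, influence, effect curve) plus a manifest with
checksums; identical configurations reproduce byte-identical outputs. The
same stages are available from a shell via `inst/cli/lakecor.R`
(`simulate`, `correlate`, `debias`, `crosslake`, `run-all`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's headline behaviour from scratch under the given
seed: the default synthetic pipeline end to end, a 60-lake trophic-state
catalog through debiasing and the weighted cross-lake model (logging each
attribute's relative influence and the endpoints of the isolated median
chl-a effect curve), and the satellite-vs-in-situ validation report, then
writes the JSON report to `--out`.
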