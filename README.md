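# entsdm — maximum-entropy habitat-suitability modelling

`entsdm` is a self-contained R implementation of the MaxEnt-style species
distribution modelling (SDM) workflow used to forecast where a species can
live under current and future climates — built for studies like the range
assessment of the cedar bark beetle (*Phloeosinus aubei*) in China, where
occurrence records plus gridded bioclimatic layers are turned into habitat
suitability maps, class-area change tables and range-centroid shifts under
SSP emission scenarios.

Everything runs from plain-text inputs (ESRI ASCII grids, occurrence CSVs)
with no external model binary: the maximum-entropy model itself, its tuning,
evaluation and all post-processing are implemented in the package (with a
compiled coordinate-descent core). A synthetic-landscape generator with a
known true niche makes the entire pipeline testable offline.

## The model

Given presence sites and a background sample of the landscape, the model is
the Gibbs distribution over cells

    q_lambda(x) = exp(lambda . f(x)) / Z,

where `f(x)` are features of the environmental covariates (linear,
quadratic, product, hinge, threshold — classes L/Q/P/H/T, each min–max
normalized to [0, 1] on the training data) and `lambda` minimizes the convex
L1-regularized objective

    -mean_presence[lambda . f] + log sum_background exp(lambda . f)
        + sum_j beta_j |lambda_j|,

with `beta_j = RM * beta_class(m) * sd_j / sqrt(m)` (per-class defaults,
`m` presences, `RM` the regularization multiplier). The familiar logistic
suitability is `p = raw * e^H / (1 + raw * e^H)` with `H` the entropy of the
fitted distribution. The pipeline around it:

1. **thin** occurrences to one per 4.5 km cell;
2. **prune** collinear layers (pairwise Pearson |r| > 0.8; the lower
   univariate-gain member of each pair is dropped);
3. **tune** over RM 0.1–4.0 (step 0.1) × all 31 feature-class subsets
   (1240 candidates), selecting by test omission < 5% and ΔAICc ≤ 2;
4. **evaluate** with 10 random 75/25 presence splits (AUC, TSS, OR10
   omission), percent contribution, permutation importance, jackknife
   gains and response curves;
5. **project** the replicate-averaged map onto scenario stacks, classify it
   (unsuitable < 0.05 ≤ low < 0.33 ≤ medium < 0.66 ≤ high), and report
   class areas (10⁴ km²), area-change percentages and the shift of the
   high-class suitability-weighted centroid (haversine distance, bearing).

## Worked example

A synthetic landscape whose true niche is driven by annual precipitation
(`bio12`) and coldest-month minimum temperature (`bio6`):

```r
library(entsdm)

sim <- simulate_landscape(landscape_spec(seed = 42))
occ <- sample_presences(sim$truth, sim$stack, n = 300, seed = 43)

occ_thin <- thin_occurrences(occ, cell_km = 4.5, anchor = c(100, 25))
#> occurrence_set: 272 records of "synthetic" (geographic)

samples <- extract_samples(sim$stack, occ_thin, seed = 44)
filt <- correlation_filter(sim$stack, threshold = 0.8, samples = samples)
#> correlation_report: 7 retained (alt, bio1, bio3, bio6, bio8, bio12, bio15),
#>   1 dropped, threshold 0.8
```

The engineered collinear layer (`bio13`, r = 0.9 with `bio12`) is pruned.
Fit and evaluate:

```r
sf <- subset_samples(samples, filt$retained)
features <- build_features(sf, classes = c("L", "Q"))
model <- fit_maxent(sf, features, rm = 1, track_contributions = TRUE)
#> maxent_model: 14 features (13 nonzero), rm = 1, gain = 0.6257,
#>   H = 7.3293, 11 sweeps (converged)

ev <- evaluate_replicates(sf, features, rm = 1, n_replicates = 10,
                          seed = 45, stack = sim$stack, keep_models = TRUE)
#>         metric      mean          sd
#>      train_auc 0.8001572 0.004986524
#>       test_auc 0.7767007 0.015884453
#>  test_omission 0.1161765 0.026352314
#>        max_tss 0.4779659 0.023220189
#>           gain 0.6408268 0.019592939
```

Mean test AUC ≈ 0.78: good presence–background discrimination on this world.
The two truth-driving variables dominate both importance measures:

```r
data.frame(percent_contribution = round(percent_contribution(model), 1),
           permutation_importance =
             round(permutation_importance(model, sf, seed = 46), 1))
#>       percent_contribution permutation_importance
#> bio12                 50.8                   54.7
#> bio6                  27.9                   42.6
#> bio1                  14.5                    0.2
#> bio8                   3.5                    2.3
#> ...
```

Classify, project a warming scenario, and account for the change:

```r
cmap <- classify_suitability(ev$averaged_map)
#> classified_map: unsuitable=839, low=903, medium=1037, high=71
bd <- class_areas(cmap, crs_mode = "geographic")
#> class_breakdown [10^4 km^2]: low 2.51, medium 2.88, high 0.20,
#>   total suitable 5.59

fut <- make_future_scenario(sim$stack, list(bio6 = 1, bio1 = 1), "warm")
fut_map <- average_projection(ev$models, fut)
ch <- area_change(bd, class_areas(classify_suitability(fut_map), "geographic"))
#>           class   current    future change_pct_2dp
#>             low 2.5086581 2.6708124           6.46
#>          medium 2.8826705 2.7797358          -3.57
#>            high 0.1973929 0.1584918         -19.71
#>  total_suitable 5.5887215 5.6090401           0.36

centroid_shift(cmap, ev$averaged_map,
               classify_suitability(fut_map), fut_map)
#>  baseline: (101.166, 26.171)  scenario: (101.059, 26.162)
#>  distance_km 10.77   bearing_deg 265.1
```

On this niche a uniform +1 sd warming overshoots the thermal optimum, so
the high class shrinks (−19.7%) and its centroid retreats westward — the
kind of reversal the real study reports under its high-emission scenario.

## Command line

```sh
Rscript inst/cli/entsdm simulate --out demo --seed 1        # synthetic world
Rscript inst/cli/entsdm run-all --config demo/config.json   # full pipeline
```

Subcommands `thin`, `filter-vars`, `tune`, `fit`, `evaluate`, `project`,
`classify`, `report`, `centroid` run the (deterministic, seeded) pipeline
up to the named stage; `selftest` asserts that every configuration default
equals the published protocol value (4.5 km thinning, |r| > 0.8, RM grid
0.1–4.0 × 31 class subsets = 1240 candidates, 10 × 75/25 replicates,
≤ 5000 iterations, 0.05/0.33/0.66 suitability cuts).

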