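# rsfate

Use–availability resource selection functions (RSFs) contrasted by litter
fate, for movement ecologists asking whether a mother's habitat selection
predicts whether her offspring survive — in particular, whether mothers use
human-proximate habitat as a protective shield against infanticidal
conspecifics.

The package implements the full analysis pipeline around that question:

* **Telemetry preparation** — dilution-of-precision filtering (`dop < 5`),
  fix-rate accounting with Welch's t-test between fate groups,
  kernel-density randomization of monitoring end dates for successful
  mothers from the observed loss dates, truncation of every bear-year to
  the mating-season analysis window, GPS cluster-site detection
  (≥3 consecutive fixes within 15 m), and logged exclusions.
* **Home ranges and availability** — 100% minimum convex polygon home
  ranges, with availability points matched 1:1 to each bear-year's retained
  relocations (third-order), or sampled over the study area (second-order).
* **Design table** — covariate extraction from raster landscapes (distances
  to habitation / road / forest road in km, NDVI, seven land-cover classes
  dummy-coded against an "other" baseline), pooled standardization, VIF
  screening, survival interactions.
* **The model** — a logistic GLMM with crossed random intercepts for bear
  identity and year, written here from first principles: penalized-Newton
  inner solves, a Laplace-approximated marginal likelihood maximized over
  fixed effects and variance components with an analytic envelope gradient.
  For a point used by animal *i* in year *t*:

  logit P(used) = x'β + (s·x)'γ + u_bear(i) + v_year(t),
  u ~ N(0, σ²_id), v ~ N(0, σ²_yr)

  where s is the litter-survival flag: main effects are the unsuccessful
  group's selection, main + interaction the successful group's. Distance
  signs are reversed for reporting so positive = selection for the feature.
* **Model selection** — AICc (−2ℓ + 2k + 2k(k+1)/(n−k−1)), Δ AICc and
  Akaike weights over a 15-model candidate set; per-interaction importance
  by systematic exclusion (ΔAICc_diff, sign-reversed for display,
  conclusive at ≥ 4).
* **Synthetic data** — a landscape + telemetry generator with known
  selection coefficients (19 successful / 11 unsuccessful bear-years,
  30-min fix schedule, ~40% of fixes DOP-contaminated, early-season litter
  losses), so the entire pipeline is testable without any proprietary
  collar data.

## Worked example

```r
library(rsfate)

g  <- grid_spec(200, 200, cell_size = 25)          # 5 x 5 km landscape
ls <- gen_landscape(g, seed = 3)
st <- simulate_study(truth = truth_config(home_radius = 1200),
                     landscape = ls, seed = 5)
pr <- prepare_study(st$bear_years, seed = 7)

annual <- lapply(st$bear_years, function(b) { b$relocations <- filter_dop(b$relocations); b })
keys   <- sapply(pr$bear_years, function(b) paste0(b$bear_id, "/", b$year))
annual <- Filter(function(b) paste0(b$bear_id, "/", b$year) %in% keys, annual)
hr  <- mcp_home_ranges(annual)
av  <- sample_study_availability(pr$bear_years, hr, seed = 11)
tab <- build_use_avail_table(pr$bear_years, av, st$landscape)

full <- model_spec(c(continuous_covariates(), landcover_classes()[1:6]),
                   c(continuous_covariates(), landcover_classes()[1:6]))
fit  <- fit_rsf(tab, full)
fit
```

```
<rsf_fit> m(dist_habitation+dist_road+dist_forest_road+ndvi+bog+TRB+clearcut+young+mid_aged+old | ...)
  n = 29148, k = 24, logLik = -18819.732, AICc = 37687.506
  variance components: bear_id 0.0723, year 0.0467
                               beta     se
(Intercept)                 -0.2963 0.1569
dist_habitation              0.1296 0.0246
...
dist_habitation_x_survival  -0.4067 0.0312
clearcut_x_survival          1.1384 0.1483
...
```

Read on the distance scale, the positive `dist_habitation` main effect
(+0.130) says unsuccessful mothers sit farther from habitation than expected
from availability (avoidance), while the negative interaction (−0.407) pulls
successful mothers the other way: main + interaction < 0, i.e. successful
mothers select proximity to humans — the generating contrast the synthetic
truth encodes. `report_coefficients(fit)` flips the distance signs and
builds the per-group ±1.96 s.e. figure; `interaction_importance()` then
ranks the survival interactions by how much AICc deteriorates when each is
removed.

The one-call version of all of the above, writing CSVs and figures to a run
directory, is:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "rsfate_run")
```

and the same stages are exposed as CLI subcommands in `inst/cli/rsfate.R`.

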