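---
title: "Habitat selection contrasted by litter fate: models and design choices"
author: "rsfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat selection contrasted by litter fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

In species with sexually selected infanticide (SSI), mothers with dependent
young may reduce offspring mortality by selecting habitat their infanticidal
conspecifics avoid. Where adult males strongly avoid human footprint, human
habitation can act as a protective "shield". `rsfate` implements the
statistical pipeline for testing this idea with GPS telemetry: contrast the
resource selection of mothers whose litters survived the mating season
against mothers who lost their litters, and quantify how much each
habitat-by-fate interaction contributes to the model.

## The model

Selection is estimated with use–availability resource selection functions
(RSFs). Each GPS relocation is a "used" point (response 1); an equal number
of random points from the same animal's annual 100% minimum convex polygon
(MCP) home range are "available" points (response 0). The model is a
logistic GLMM with logit link,

\[
\mathrm{logit}\,P(y_{ij}=1) = \mathbf{x}_{ij}'\boldsymbol\beta
 + (s_i \cdot \mathbf{x}_{ij})'\boldsymbol\gamma
 + u_{\mathrm{bear}(i)} + v_{\mathrm{year}(i)},
\]

with landscape covariates \(\mathbf{x}\) (distances to habitation, road and
forest road in km; NDVI; six land-cover dummies with "other" as baseline),
the litter-survival flag \(s_i \in \{0, 1\}\) interacting with the
covariates, and crossed random intercepts for bear identity and year,
\(u \sim N(0, \sigma^2_{id})\), \(v \sim N(0, \sigma^2_{yr})\). Main effects
read as the unsuccessful group's selection; main effect + interaction as the
successful group's. Models are fitted on the distance scale; for reporting,
distance-coefficient signs are reversed so positive values read "selection
for" the feature.

Under the exponential RSF, \(w(\mathbf{x}) = \exp(\boldsymbol\beta'
\mathbf{x})\), the logistic slope coefficients estimated from the
use–availability contrast converge to the RSF coefficients, which is also
the property the synthetic generator inverts.

### Likelihood and the Laplace approximation

The marginal likelihood integrates the crossed random intercepts out of the
Bernoulli likelihood. Quadrature is impractical for crossed factors, so the
package maximizes a Laplace approximation: for given \((\boldsymbol\beta,
\sigma^2)\), the random-effect mode \(\hat{u}\) is found by penalized Newton
iterations, and

\[
\ell_{\mathrm{Lap}} = \ell(\boldsymbol\beta, \hat u)
 + \log \phi(\hat u; 0, D) + \tfrac{q}{2}\log 2\pi
 - \tfrac12 \log\det H,
\]

with \(H\) the curvature of the penalized objective at the mode and \(q\)
the number of random levels. The fitter maximizes \(\ell_{\mathrm{Lap}}\)
over \(\boldsymbol\beta\) and \(\log\sigma^2\) jointly: a fast first stage
profiles \(\boldsymbol\beta\) at the joint penalized mode, and a refinement
stage then optimizes the exact Laplace objective with the analytic envelope
gradient

\[
\nabla_{\boldsymbol\beta}\,\ell_{\mathrm{Lap}} = X'(y-\mu)
 - \tfrac12 \sum_i c_i \dot w_i\, \mathbf{t}_i,
\]

where \(c_i = z_i'H^{-1}z_i\), \(\dot w_i = w_i(1-2\mu_i)\) and
\(\mathbf{t}_i\) is the total derivative of the linear predictor following
the mode. The refinement matters: profiling alone leaves
\(O(1/\text{group size})\) bias in \(\hat{\boldsymbol\beta}\) relative to
the adaptive-quadrature optimum, which the tests bound at \(10^{-2}\) per
coefficient on toy single-factor data (where a 64-node adaptive
Gauss–Hermite oracle is available). With both variance components at zero
the fit reduces exactly to maximum-likelihood logistic regression, verified
against `stats::glm` at \(10^{-6}\).

Everything is maximum likelihood (no REML analogue), because candidate
models differ in their fixed effects and are compared by AICc:
\(\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)\), with \(k\) counting fixed
effects (intercept, mains, survival main, interactions) plus the two
variance components, and \(n\) the number of used + available rows. Both
conventions are recorded in every fit because neither is canonical in the
literature. Standard errors come from the fixed-effect block of the inverse
curvature of the joint penalized objective (the usual conditional GLMM
covariance); uncertainty in \(\sigma^2\) is not propagated.

### Numerical choices

* Inner Newton: step-halving line search, convergence when the step falls
  below 1e-9; a tiny ridge is added only if the curvature factorization
  fails.
* Outer search: L-BFGS-B on \(\log\sigma^2\) bounded in \([\log 10^{-10},
  \log 10^4]\); variance components that finish at the floor are reported
  as 0 (boundary fits).
* Separation heuristic: any standardized \(|\hat\beta| > 10\) raises a
  warning.
* `log(1+e^\eta)` is computed in a form stable for \(|\eta|\) large; the
  synthetic generator refuses \(|\eta| > 50\) on a home disc (acceptance
  probabilities would underflow) and advises rescaling the coefficients.

## Model selection and interaction importance

Fifteen candidate models are built from three thematic term groups —
anthropogenic distances, land cover, vegetation (NDVI): the all-terms model
with interactions on all terms / anthropogenic only / land cover only /
none; each group and each pairwise union with and without interactions on
its terms; and the intercept-only null. The published candidate list is not
machine-readable, so this default follows the described pattern and is fully
overridable (`build_candidate_set(specs = ...)`); a real-data reanalysis
should supply the original list. Models are ranked by AICc with Akaike
weights; \(\Delta\mathrm{AICc} \ge 4\) flags a model inconclusive.

The importance of each survival interaction in the best model is measured by
refitting without that interaction (keeping the covariate's main effect) and
recording \(\Delta\mathrm{AICc}_{\mathrm{diff}} = \mathrm{AICc(full)} -
\mathrm{AICc(reduced)}\); the reported importance is its negative (high =
important) and the conclusiveness threshold of 4 is applied on the reported
scale, matching how the importance figure is drawn.

Collinearity is screened with VIFs (\(1/(1-R^2_j)\), OLS, flagged at 3) over
the continuous covariates. The six land-cover dummies of the single
seven-class factor are deliberately not screened against each other: their
mutual VIFs are inflated by construction at realistic prevalences, and
ejecting dummy levels for mechanical collinearity would misrepresent the
factor.

## Telemetry preparation

* DOP filter: relocations with dilution of precision \(\ge 5\) are removed
  (strictly `dop < 5` retained, including removal of the boundary value).
* Analysis period: 1 May until the litter's loss date (unsuccessful) or a
  randomized end date (successful), never beyond the last observed loss
  date. End dates are drawn from a Gaussian-kernel KDE (Silverman bandwidth,
  day resolution) over the observed loss dates, rejected outside
  [season start, truncation]; the lower bound is the season start because
  observed end dates can precede the earliest loss. Draws are independent
  across bear-years (whether the original procedure stratified by year is
  unstated; independence is the simpler assumption).
* A mother with partial litter loss is excluded (exposure ill-defined), and
  a minimum-data rule (defaults: ≥2 monitored days, ≥50 retained fixes)
  excludes bear-years too thin to support a selection estimate; both with
  logged reasons.
* GPS cluster sites (≥3 consecutive fixes within 15 m) are detected with the
  radius measured about the running centroid — a cluster is a revisited
  place, so the centroid rule is the natural reading — with a
  first-fix-anchored alternative behind a flag.
* Welch's t-test (via `stats::t.test`) compares fix rates between fate
  groups.

MCP home ranges use all of a bear-year's DOP-filtered fixes (the "annual"
range), not only the truncated season, with a flag to restrict; availability
is matched 1:1 to the retained (post-filter, post-truncation) used points,
since those are the rows the models see. Second-order availability
(study-area scale) replaces the MCP with the pooled extent of all home
ranges, or any supplied polygon — the true study-area boundary is not
reproducible from the text.

## The synthetic generator

The generator exists so the whole pipeline can be validated against known
truth without the proprietary collar data. It emulates:

* a 25 m landscape grid with habitations (homogeneous point process), roads
  and forest roads (random crossing polylines), seven land-cover classes
  (smoothed Gaussian field thresholded at target proportions) and NDVI
  (independent smoothed field rescaled into a realistic range);
* 19 successful and 11 unsuccessful bear-years (16 and 10 distinct mothers:
  a few are monitored in two years, making bear and year genuinely crossed);
* a 30-min fix schedule with 95% acquisition and a DOP mixture putting ~40%
  of fixes at DOP ≥ 5, so the post-filter fix rate lands near the observed
  ~57–61%;
* litter-loss dates from Beta(2, 3) rescaled onto 1 May–16 June — an
  assumption standing in for an empirical loss-date density that is not
  machine-readable, deliberately exposed in `truth_config()`;
* group-specific exponential selection: used locations are drawn by
  rejection sampling uniform proposals in a circular home range, accepted
  with probability \(\exp(\eta - \eta_{\max})\). Coefficients act on
  landscape-standardized continuous layers (z-scored over all cells) plus
  raw 0/1 indicators; the defaults carry the magnitudes and signs of the
  published estimates, mapped to the distance scale (e.g. habitation +0.210
  for unsuccessful, −0.524 for successful mothers).

What it does **not** emulate: temporal autocorrelation of fixes (points are
conditionally independent given the RSF, which is also how the fitted model
treats them), real satellite-band processing, road-network topology, terrain,
or multi-season demography. Home ranges are generated as discs, but nothing
downstream assumes that shape — MCPs are re-estimated from the simulated
fixes. Passing the recovery tests therefore shows the estimator is correct
for data generated by its own model class; it does not certify behaviour
under autocorrelated or irregular real telemetry.

Because the generator standardizes over the landscape while the fitted model
standardizes over the pooled point sample, generating coefficients are
mapped onto the fitted scale (`truth_fixed_effects()`, multiplying by
`sd_sample / sd_landscape`) before recovery is assessed — the two scales
differ because home ranges subsample the landscape's covariate range.

## Validation harnesses and problem sizes

`recovery_harness()` runs 20 replicate studies at the study's group sizes
(19 + 11 bear-years, ~500 retained fixes each after filtering and
truncation, ~30,000 model rows) and checks per-coefficient ±2 s.e. coverage
and the qualitative human-shield sign pattern. Every replicate is a complete
fresh study — 10 × 10 km landscape, telemetry, fates, availability — so that
coverage is not conditioned on one particular landscape's road layout. By
default the harness samples availability from the generating home discs
(`availability = "disc"`), so that it measures recovery of the estimator
itself; `availability = "mcp"` runs the full pipeline instead, where the
hull stage contributes the contraction attenuation quantified below.
`importance_harness()` places the group contrast only on
distance-to-habitation (or nowhere, for the null), simulating selection only
on the covariates it models so that spurious interactions cannot arise from
group differences in exposure to unmodelled land-cover effects, and checks
that the habitation × survival interaction tops the importance ranking (or
that nothing is conclusive); it runs on a 2-h fix schedule — also a standard
collar configuration — so each of its 100 replicate fits stays light.

Two finite-sample properties of the prescribed design are worth knowing
when reading recovery results. First, availability polygons are the hulls
of the very points they serve, so they slightly under-cover the least-used
fringe of the true range, attenuating the strongest coefficients by a few
percent (classic MCP contraction). Second, random-intercept shrinkage can
leak between-range contrasts into slope estimates for covariates whose
variation is mostly between home ranges rather than within them (distances
to a handful of roads being the canonical case). Both effects are
properties of the analysis design itself, not of this implementation, and
both are small relative to 2 s.e. at the study's size.

The quadrature oracle (`lme4::glmer`, `nAGQ = 64`) is only usable for a
single random factor; the crossed fitter is therefore cross-checked against
`glmer`'s own Laplace fit on crossed toy data, and against the
adaptive-quadrature optimum on single-factor data. The toy datasets use a
generating variance of 0.15, the magnitude reported for bear identity in
the motivating study.

## Known limitations

* The published coefficient values themselves are not reproducible — the
  underlying telemetry is proprietary — so all validation is against
  synthetic ground truth and independent numerical oracles.
* The published variance components (0.151, 0.002) are on an unstated scale;
  this package reports variances.
* With availability matched per bear-year, the survival main effect is
  design-confounded (used:available odds are fixed at 1:1); it is retained
  for hierarchical well-formedness whenever interactions are present and
  should not be interpreted.
* No random slopes, no spatial/temporal autocorrelation terms, no Bayesian
  path, no kernel home ranges; second-order availability uses a pooled
  extent unless a study-area polygon is supplied.

## A worked run

```{r}
library(rsfate)
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "rsfate_run")
res$selection        # AICc ranking of the 15 candidates
res$importance       # interaction importance, threshold 4
res$coefficients     # per-group estimates, distance signs reversed
```

The same stages are available from a shell via the thin CLI wrapper
(`inst/cli/rsfate.R`): `simulate`, `prep`, `homerange`, `build-table`,
`select`, `report`, `run-all`.
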