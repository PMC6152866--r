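# occumap

Occupancy–detection modelling for multi-method wildlife surveys, with
constrained all-subsets model selection, parametric-bootstrap
goodness-of-fit testing, and raster prediction of occupancy and stacked
relative species richness.

The package is aimed at ecologists analysing repeat detection/non-detection
data collected with several sampling methods at once — live traps checked
nightly, daily bird counts, nocturnal spotlight searches, and motion-sensor
cameras binned into weekly occasions — who want per-species occupancy and
per-method detectability estimates that correct for imperfect detection,
and maps of where species (and species richness) are predicted to be.

## The model

Surveys are reduced to per-species detection histories: for site *i* and
occasion *j*, `y_ij = 1` if the species was detected, 0 if it was surveyed
without detection, and missing if it was not surveyed. The latent
occupancy state and the observations are two coupled Bernoulli processes:

```
z_i      ~ Bernoulli(psi_i)          true occurrence at site i
y_ij|z_i ~ Bernoulli(z_i * rho_ij)   detection on occasion j
```

with logit links `logit(psi_i) = x_i' beta` (site covariates, optionally
quadratic) and `logit(rho_ij) = gamma_{m(j)} + w_i' gamma` where `m(j)` is
the sampling method of occasion *j*, entering as an observational-level
factor. Maximising the marginal likelihood

```
L_i = psi_i * prod_j rho_ij^y_ij (1 - rho_ij)^(1 - y_ij)
      + (1 - psi_i) * 1[all observed y_ij = 0]
```

gives ML estimates, Wald standard errors (inverse observed information),
and AIC. Around the core model the package provides:

* **Detection-history construction** — daily/weekly occasion collapsing
  with an any-detection rule over sub-events, per-method histories
  appended into one matrix with ragged designs handled as missing data.
* **Covariate preparation** — Spearman collinearity screening (|rho| > 0.7
  discards the lower-priority member of a pair), centring/standardising
  with constants reused at prediction time, quadratic design matrices
  under marginality.
* **Model selection** — all-subsets enumeration capped at one covariate
  term per 10 detection sites, AIC ranking, a strict delta-AIC < 6
  confidence set, boundary-estimate and goodness-of-fit screening, and a
  constant-occupancy fallback.
* **Goodness of fit** — parametric bootstrap (simulate from the fitted
  model, refit, compare) of three observation-level statistics: sum of
  squared errors, Freeman–Tukey, and Pearson chi-squared.
* **Mapping** — inverse-logit prediction onto covariate rasters,
  environmental-domain masking to the sampled covariate ranges, buffered
  geographic-range masks for restricted-range species, and cellwise summed
  occupancy as a relative richness index.
* **Synthetic data** — a generator for correlated covariate landscapes,
  sites, and multi-method survey records with known parameters, so the
  whole pipeline is testable end to end.

Rasters are handled by a lightweight in-package grid class (`cov_stack`)
serialised as plain-text grids with a JSON sidecar.

## Worked example

Simulate one species surveyed by cage traps (4 nights) and cameras
(5 weeks) at 300 sites, fit the generating model, and map it:

```r
library(occumap)

stack <- gen_landscape(40, 40, c("ruggedness", "time_since_fire"), seed = 11)
sites <- gen_sites(stack, 300, seed = 12)
truth <- true_parameters(
  "quoll", beta_intercept = -0.5,
  beta_terms = data.frame(covariate = "ruggedness", degree = 1L, coef = 1),
  gamma_intercepts = c(cage_trap = -1.2, camera = 0.2))
design <- survey_design(c("cage_trap", "camera"),
                        c(cage_trap = 4L, camera = 5L))
records <- simulate_surveys(sites, truth, design, seed = 13)$records

history <- build_history(records, "quoll")
n_detection_sites(history)
#> [1] 122

std <- standardize_covariates(sites)
spec <- model_spec(data.frame(covariate = "ruggedness", degree = 1L))
fit <- fit_occu(spec, history, std$table, scaling = std$scaling)
fit
#> <fitted_occu> psi(~ruggedness) p(~method)
#>   logL = -880.3849, K = 4, AIC = 1768.7699, converged = TRUE
#>          (Intercept) ruggedness p:cage_trap p:camera
#> estimate     -0.4142     0.7704     -1.1089   0.1018
#> se            0.1267     0.1421      0.1050   0.0826
```

The fitted coefficients sit close to the generating values (−0.5, 1,
−1.2, 0.2). Site-averaged estimates put mean occupancy at 0.41 ± 0.027,
and per-occasion detectability at 0.248 ± 0.020 for one night of cage
trapping versus 0.525 ± 0.021 for one week of camera deployment — the
kind of method comparison the model is for:

```r
mean_estimates(fit, history, std$table)

parametric_bootstrap(fit, history, std$table, B = 200, seed = 14)
#> <gof_result> B = 200
#>       statistic     t_obs   p_value
#> 1           sse  352.1712 0.4477612
#> 2 freeman_tukey  491.7744 0.4378109
#> 3       pearson 2765.7756 0.2189055

surface <- predict_raster(fit, stack, species = "quoll")
#> <occupancy_surface> quoll, 40 x 40 cells, 0 missing
```

No statistic rejects the (correct) model. For a multi-species analysis —
collinearity screening, per-species dredging under the detections cap,
selection, GoF, mapping and richness stacking in one call — see
`run_pipeline()` and the methods vignette
(`vignettes/occupancy-detection-methods.Rmd`).

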