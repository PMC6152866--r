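---
title: "Methods: multi-method occupancy-detection modelling in occumap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method occupancy-detection modelling in occumap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occumap)
```

## The model and its assumptions

occumap fits single-season site-occupancy models to multi-method repeat
detection/non-detection data. The latent state $z_i \sim
\mathrm{Bernoulli}(\psi_i)$ is whether the species occurs at (or uses)
site $i$ over the survey period; conditional on $z_i$, each surveyed
occasion yields $y_{ij} \mid z_i \sim \mathrm{Bernoulli}(z_i\,
\rho_{ij})$. Both probabilities are modelled on the logit scale:
$\psi_i$ as a linear (optionally quadratic) function of standardised site
covariates, and $\rho_{ij}$ with one intercept per sampling method — the
method is an observational-level factor, varying by occasion rather than
by site — plus optional site-level detection covariates shared across
methods.

The key assumptions are the usual ones for this model class:

* **Closure** within the survey period: $z_i$ does not change across
  occasions (or movement in and out of the site is random, in which case
  $\psi$ reads as "use" rather than strict occupancy).
* **No false positives**: a detection implies presence, so all the
  evidence against occupancy comes from all-zero histories.
* **Independence** of occasions given $z_i$, and of sites given the
  covariates.

The marginal likelihood integrates $z_i$ out analytically:
$$L_i = \psi_i \prod_{j \in \mathrm{obs}(i)} \rho_{ij}^{y_{ij}}
(1-\rho_{ij})^{1-y_{ij}} + (1-\psi_i)\,
\mathbf{1}\!\left[\textstyle\sum_{j \in \mathrm{obs}(i)} y_{ij} = 0\right],$$
where $\mathrm{obs}(i)$ are the occasions actually surveyed. Missing
occasions are a first-class concept, not zeros: sites surveyed for three
rather than four trap nights simply have a missing fourth column, and a
site never visited by a method has that method's whole column block
missing. A site with no surveyed occasion at all carries no information
and is dropped with a warning. `brute_force_likelihood()` computes the
same quantity by explicit enumeration of $z_i \in \{0,1\}$ and exists
purely as an independent test oracle for the fast vectorised path.

With a single occasion per site, $\psi$ and $\rho$ enter the likelihood
only through their product, so they are not separately identifiable; the
test suite asserts this flat profile explicitly, and `fit_occu()` warns
when no site has two or more occasions.

## Detection histories

Raw survey records are one row per site, species, method, occasion and
sub-event. Collapsing applies an any-detection rule twice: sub-events
within an occasion (e.g. three ten-minute bird counts within a day)
collapse to a single 0/1, and occasions are the unit of repeat sampling —
one day/night for live traps, bird counts and spotlight searches
(`"daily"`), one week for cameras (`"weekly"`). Occasion indices are taken
as pre-binned integers; calendar parsing is out of scope because the
designs this package targets are fixed-length. Per-method matrices are
appended column-wise in a reproducible method order (lexicographic by
default, overridable), and the per-column method label is what the
detection model's factor sees. Collapsing an already-collapsed matrix is
idempotent, and appending preserves per-method detection counts exactly;
both are asserted as properties in the tests.

## Covariate preparation

* **Collinearity screening**: pairwise Spearman rank correlations; while
  any retained pair has $|\rho| > 0.7$ (strict), the pair with the largest
  $|\rho|$ is resolved by discarding its lower-priority member. Priority
  is a user-supplied ordering (defaulting to column order), which makes
  ad hoc published choices — e.g. dropping a minimum-temperature variable
  in favour of rainfall — reproducible by configuration. Screening uses
  all fitted sites; a constant covariate is an error because its rank
  correlation is undefined.
* **Standardisation**: $(x - \bar x)/s$ with the sample sd ($n-1$); the
  constants are stored and re-applied verbatim to new sites and raster
  cells at prediction time, which matters because a raster's own mean is
  generally not the sites' mean.
* **Quadratic terms** are computed on the standardised scale and obey
  marginality (a squared term requires its linear term): the all-subsets
  enumeration stays interpretable that way. Two neighbourhood fire
  metrics, fire extent and fire patchiness, refuse quadratic terms by
  default (`QUADRATIC_BANNED`) since their response is treated as
  monotone.
* **Coarsening** (`reclassify_raster`) takes block means of finite cells;
  resolution reduction is cosmetic for map delivery, so a mean is the
  neutral choice.

## Fitting: numerical choices

Optimisation is quasi-Newton (BFGS) on the unconstrained logit-scale
coefficients with the analytic gradient, relative tolerance $10^{-10}$,
and (by default) 5 jittered restarts seeded from the supplied seed, the
best optimum kept. Starting values: the occupancy intercept from the
logit of naive occupancy (share of sites with at least one detection,
clipped to [0.05, 0.95]); each method's detection intercept from the
logit of that method's detection frequency among detected sites; slopes
at zero. Standard errors come from the inverse observed information
(numerical Hessian at the optimum).

Degenerate fits are flagged rather than failed: `boundary_flag` is set
when the information matrix is numerically singular or when every fitted
$\psi_i$ (or every $\rho_{ij}$) is within $10^{-4}$ of 0 or 1 — the
classic symptom of too few detections, in which case the Wald machinery
is meaningless and model selection treats the candidate as unusable.
Detection probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside
the likelihood, and per-site likelihood contributions floored at
$10^{-300}$, so the objective stays finite along extreme search paths.

Method intercepts use one-intercept-per-method coding (no reference
cell); it is equivalent to contrast coding and makes per-method
detectability directly readable from the coefficients.

`mean_estimates()` averages $\hat\psi_i$ over fitted sites and
$\hat\rho_{ij}$ over each method's surveyed site-occasions, with
delta-method standard errors from the coefficient covariance. Whether a
published "mean ± SE" is the delta-method SE of the mean or the spread of
site-level estimates is ambiguous in general, so both are reported: `se`
is the delta-method SE, `sd_sites` the spread.

## Model selection

Candidates are all subsets of the screened occupancy covariates (each
covariate absent, linear, or linear + quadratic where allowed) crossed
with all subsets of the detection covariates. The complexity cap is
`floor(n_detection_sites / 10)` covariate terms — each linear or
quadratic term counts one; intercepts and the method factor do not count,
because the cap is about covariates, not parameters. The cap applies
jointly across the occupancy and detection parts (the conservative
reading; a $\psi$-only cap is a configuration away since the detection
candidate list can be emptied). Species with fewer than 10 detection
sites therefore get the constant-occupancy model only, and are fitted and
flagged rather than dropped. Detection candidates default to time since
fire, fire frequency and terrain ruggedness — covariates that plausibly
change how visible animals are to an observer — and are dredged alongside
the occupancy candidates.

Converged fits are ranked by AIC ($-2\log L + 2K$, with $K$ counting all
coefficients including intercepts and method intercepts), ties broken by
fewer parameters then enumeration order, and the confidence set is
$\Delta\mathrm{AIC} < 6$ — strictly: a model at exactly 6.0 is out.
`select_best()` walks that set in rank order and rejects candidates that
are boundary-flagged, fail any goodness-of-fit statistic (p ≤ α, default
0.05), or are vetoed by a user screen. Screens are pluggable predicates
`function(fit) TRUE/FALSE`; expert map-realism review belongs there,
because expert judgment is not reproducible inside a package — the
default accepts everything that is not boundary-flagged. If the whole set
is rejected the constant-occupancy model (with the method factor) is
fitted as the fallback; if even that fails to converge, the species is a
hard error for the caller to handle.

## Goodness of fit

`parametric_bootstrap()` simulates $B$ datasets from the fitted model on
the observed design and missingness pattern, refits the same
specification to each (warm-started from the fitted coefficients — a
speed choice; the refit is still run to full tolerance), and compares
observed and simulated values of three observation-level statistics
computed on $\hat y_{ij} = \hat\psi_i \hat\rho_{ij}$ over surveyed cells:

* $\mathrm{SSE} = \sum (y - \hat y)^2$
* Freeman–Tukey $= \sum (\sqrt{y} - \sqrt{\hat y})^2$
* Pearson $= \sum (y - \hat y)^2 / (\hat y (1 - \hat y))$, the
  binomial-variance denominator clipped to $[10^{-6}, 1-10^{-6}]$ — a
  plain $\hat y$ denominator explodes on all-zero histories.

P-values use the plug-in convention $p = (1 + \#\{t^{sim} \ge
t^{obs}\})/(B+1)$, which cannot reach zero at finite $B$. All three
statistics share one replicate stream. A replicate whose refit does not
converge is redrawn; more than 10% redraws flags the result unstable.

One property of this construction is worth knowing when reading p-values.
For 0/1 data, $y^2 = y$ and $\sqrt y = y$, so each statistic is *linear*
in $y$ given the fitted values, and the per-replicate refit absorbs most
of what the fitted values respond to. The SSE and Freeman–Tukey p-values
are therefore strongly conservative under a correct model — they
concentrate near 0.5 rather than being uniform — while the Pearson
statistic, whose weights vary sharply across cells, remains approximately
uniform. The practical consequence: the default screen (any p ≤ 0.05)
almost never rejects an adequate model, and its power against misfit
comes mostly from the Pearson statistic. The acceptance tests measure
exactly this: a type-I-control check passes for all three statistics, and
the distributional-uniformity check passes for Pearson and documents the
conservatism of the other two.

## Mapping

`predict_raster()` standardises each cell with the fitting-time constants
and applies the inverse-logit occupancy predictor; a cell missing any
model covariate stays missing. Two masks only ever remove cells:

* **Environmental domain**: a cell passes iff every selected covariate is
  inside the closed interval $[\min, \max]$ observed at the fitted sites.
  The sampled extremes are the reproducible default for "not far outside
  what was sampled"; an optional symmetric quantile trim tightens the
  interval for users who want "much higher/lower" to bite earlier, but no
  particular trim value is baked in. Offshore or otherwise disjoint areas
  are handled by a user-supplied mask, not hard-coded geography.
* **Geographic range** for restricted-range species: cells whose centres
  lie within a buffer distance (e.g. 5 km) of a region grid, computed by
  a distance transform on cell centres. The same mask subsets the sites
  before fitting and clips the predictions afterwards, so estimates are
  relative to the species' expected range.

`stack_richness()` sums predicted occupancy cellwise across species. The
result is a relative richness index — a summed probability, not an
expected species count. Species whose selected model is
constant-occupancy are excluded from richness maps (their flat surfaces
are still written per species): a constant layer adds no spatial
information and would only shift the index. A cell missing in some
surfaces contributes the available ones, with a per-cell coverage count
reported alongside; it is missing only where every surface is.

Because no geospatial raster stack is required beyond regular grids, the
package carries its own minimal `cov_stack` class (matrices + origin +
cell size) serialised as plain-text TSV grids with a JSON sidecar naming
layers and scaling constants.

## The synthetic-data generator

`gen_landscape()` draws one grid per covariate from a multivariate
Gaussian with a user-supplied cross-covariate correlation, smooths each
layer with a shared Gaussian kernel (default sd 3 cells) so neighbouring
cells are similar — smoothness is what makes domain-masking and
extraction tests meaningful — and re-standardises each layer. Because the
smoother is the same linear operator for every layer, the cross-covariate
correlation survives it, and a pair generated at correlation 0.9 reliably
trips the 0.7 screening rule. `gen_sites()` samples distinct complete
cells; `simulate_surveys()` draws $z_i$ once per site and Bernoulli
detections per method, occasion and sub-event, with detection covariates
as site-level constants broadcast to all occasions (no per-occasion
weather effects are simulated; the target designs have none). The default
`default_design()` emulates a multi-method monitoring visit: cage,
Elliott and pit traps over four nights, three daily bird surveys of three
ten-minute counts, three spotlight nights, and five weekly camera
occasions, at around 300 sites; species parameters are chosen per study
to span occupancy from a few percent to ~0.8 and per-occasion
detectability from ~0.01 to 0.9.

What the generator does *not* emulate, and what passing tests therefore
do not establish about field data: residual spatial autocorrelation
beyond what the smooth covariates induce, real fire-scar or climate
dynamics behind the covariates, observer heterogeneity, misidentification
(false positives), or abundance-driven heterogeneity in detectability.

## Problem sizes and verification

All expected values in the tests are either hand-computed, produced by an
independent oracle (latent-state enumeration, a 0.001-resolution grid
search, closed-form detection probabilities, exhaustive enumeration
counts), or calibrated by simulation with known truth. The statistical
acceptance checks use problem sizes chosen to give stable Monte Carlo
behaviour at desk scale: 100 random oracle instances; 200 replicate
datasets of 300 sites for Wald coverage (target [0.90, 0.98]) and
mean-occupancy bias (< 0.02); 100 replicates of 500 sites for the
all-subsets recovery rate (generating model retained in ≥ 85% of
$\Delta\mathrm{AIC}<6$ sets); 50 outer replicates at $B = 100$ for
bootstrap calibration; and 20 replicates across 100/300/1000 sites for
the richness-error trend. `scripts/acceptance.R` re-runs scaled versions
of the same computations from a single seed and writes the measured
quantities as JSON.

## Known limitations

Single-season (static) occupancy only; no Bayesian estimation; no
abundance-induced detection heterogeneity (Royle–Nichols) or observer
effects; no overdispersion adjustment (c-hat/QAIC); richness maps carry
no propagated uncertainty. The goodness-of-fit conservatism discussed
above means a "pass" is weak evidence of fit for the SSE and
Freeman–Tukey statistics.
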