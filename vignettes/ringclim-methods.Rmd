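---
title: "Dendroclimatic water-balance modelling with ringclim: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendroclimatic water-balance modelling with ringclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringclim)
```

# Overview

`ringclim` implements a complete dendroclimatic analysis chain for
temperate, beech-dominated forest stands:

1. **Climate engine** — harmonize daily meteorological series, estimate
   global radiation from sunshine fraction, extend the record to 2100 by
   cyclically replaying a historical window (the *looped baseline*), and
   apply seasonal delta-change scenarios (RCP-style temperature offsets
   and precipitation multipliers).
2. **Phenology** — model leaf unfolding (LU, BBCH-11) and leaf coloring
   (LC, BBCH-94) of *Fagus sylvatica* to gate transpiration.
3. **Water balance** — a daily single-store model producing soil
   moisture, relative extractable water (REW), potential and actual
   transpiration, drainage and snowpack per site.
4. **Growth factors** — seven seasonal climate/water summaries per site
   and year, with one- and two-year lags, standardized per stratum.
5. **Age detrending** — a species-specific age curve whose residual
   (observed minus age-expected ring width) carries the climate signal.
6. **Sensitivity** — linear mixed-effects regression of residuals on
   standardized growth factors with a site random intercept and backward
   AIC elimination.
7. **Projection** — the fitted model driven by scenario growth factors,
   summarized over 20-year periods as deltas against the baseline.

A **synthetic-data module** generates all inputs with known ground truth
(weather, soil-moisture observations, phenological events, ring series),
so every stage — and the pipeline end to end — is validated without any
field data.

# The age curve

Expected ring width at cambial age $a$ is

$$ w_{age}(a) = \frac{p_n}{a} + p_s + w_{min}
   - 10\,k\,\ln\!\bigl(1 + e^{0.1 (p_m - a)}\bigr), \qquad
   k = \frac{w_{min} - w_{50}}{p_m - 50}, $$

a hyperbolic juvenile decline plus a softplus-smoothed linear transition
that levels off at $p_s + w_{min}$ for old trees. $w_{50}$ anchors the
width near age 50 and $p_m$ is the transition age. The residual
$w_{res} = w_{obs} - w_{age}$ is the response of all later modelling:
positive residuals indicate favourable growing conditions.

Two numerical points deserve mention:

* The softplus is evaluated as $x + \ln(1+e^{-x})$ for large arguments,
  so the curve is finite at any age.
* **$w_{min}$ is an assumption, not a fitted parameter.** The curve
  depends on $(p_s + w_{min})$ and $k$ only, so fitting all five
  parameters is non-identifiable: any shift of $w_{min}$ can be absorbed
  by $p_s$ and $w_{50}$. `fit_age_curve()` therefore fixes $w_{min}$
  (default: the smallest observed per-age mean width) and estimates
  $p_n, p_s, w_{50}, p_m$ by bounded Levenberg–Marquardt least squares on
  the per-age mean series assembled across trees, multistarted over
  $p_m \in \{80, 120, 160, 220\}$. $r^2$ is reported against the
  unweighted per-age means. Perfectly constant series short-circuit to a
  flat curve and are flagged.

# The water balance model

A single bucket of depth `root_depth` (mm) holds plant-available water
between the wilting point $\theta_{wp}$ and the holding capacity
$\theta_{hc}$ (volumetric fractions). Relative extractable water is

$$ REW = \frac{\theta - \theta_{wp}}{\theta_{hc} - \theta_{wp}}
   \in [0, 1], $$

with 0.4 marking the onset of severe and 0.7 of (at least) mild water
deficit. Stress-day counts use strict `<` by default (configurable),
and severe days are a subset of mild days on every window.

The daily flux order is fixed for reproducibility: (1) precipitation
falls as snow below 0&nbsp;°C, otherwise as rain; (2) degree-day melt
(default 3&nbsp;mm&nbsp;°C⁻¹&nbsp;d⁻¹) releases the snowpack, with
same-day snowfall available for melt; (3) throughfall is rain net of
in-leaf canopy interception (default 15&nbsp;%) plus melt; (4) potential
transpiration is `canopy_coef` × FAO-56 reference evapotranspiration,
gated by leaf phenology (dormant-season coefficient 0 by default);
(5) actual transpiration is reduced linearly below the critical REW,
$T_{act} = T_{pot}\min(1, REW/0.4)$ (the standard Granier-type closure),
and additionally capped by extractable water so $\theta$ never falls
below $\theta_{wp}$; (6) the store is updated and (7) water above
$\theta_{hc}$ drains. The daily mass balance — rain + melt −
interception − $T_{act}$ − drainage = Δstorage — closes to numerical
precision and is asserted over 10,000 random forcing days in the test
suite. Soil evaporation is not carried as a separate flux; interception
absorbs canopy losses, because only transpiration enters the growth
factors (the climatic water balance is precipitation minus *actual
transpiration*, with gross precipitation used in the difference).

Reference evapotranspiration follows FAO-56: net shortwave with albedo
0.23, net longwave from the Stefan–Boltzmann term with humidity and
cloudiness corrections (the ratio of measured to clear-sky radiation is
bounded below at 0.3, the FAO overcast limit, so a zero-radiation
saturated day yields zero demand), psychrometric constant from
barometric pressure at site elevation, and zero soil heat flux at the
daily step.

Radiation is estimated from sunshine fraction by the Ångström–Prescott
relation $R_g = R_a(a + b\,n/N)$ with the FAO default coefficients
$a = 0.25$, $b = 0.50$ (configurable; no local calibration is assumed).
For sloping plots the direct-beam fraction — derived from the same
Ångström partition, $b\,n/N/(a + b\,n/N)$ — is rescaled by the ratio of
daily direct irradiance on the tilted plane to the horizontal plane,
obtained by stepping the sun across the sky at 5-minute resolution;
the diffuse fraction is left untouched.

One parameterization (default: $\theta_{wp} = 0.12$,
$\theta_{hc} = 0.32$, root depth 600&nbsp;mm, `canopy_coef` 0.8 —
plausible for a stagnic-cambisol beech stand, giving annual
transpiration sums of roughly 300–380&nbsp;mm under the packaged
synthetic climate) is applied to all sites. `calibrate_wbm()` fits
$\theta_{wp}, \theta_{hc}$ and root depth to an observed soil-moisture
series by bounded L-BFGS-B from a fixed-seed Latin-hypercube multistart,
and flags solutions on the bounds.

# Phenology

Leaf unfolding accumulates photoperiod-weighted forcing from January 1:
$\max(T - T_{base}, 0) \cdot (\text{daylength}/24)^{e}$; LU is the first
day the sum reaches $F_{crit}$. The power of normalized daylength is the
minimal monotone photoperiodic weight; $e = 0$ recovers pure growing
degree days. If the threshold is never reached the year is flagged
(`NA`). Pointwise-warmer springs can never delay LU, a property asserted
by simulation.

Leaf coloring is linear in two window-mean temperatures,
$LC = c_0 - c_s \bar T_{spring} + c_a \bar T_{summer}$ with
$c_s, c_a \ge 0$: cool late springs and warm late summers both delay
senescence. Default windows are May–June and August–September (the
literature gives "late spring" and "late summer to early autumn" without
dates; these are documented substitutes, not reconstructions). Defaults
($T_{base} = 4$&nbsp;°C, $e = 1$, $F_{crit} = 110$, $c_0 = 283$,
$c_s = 1.5$, $c_a = 2$&nbsp;d/°C) give LU in late April and LC in
mid-October under the packaged synthetic climate, and — because
$c_a > c_s$ — a uniform warming lengthens the growing season, more
through an earlier start than a later end.

`fit_phenology()` fits LU by grid search over $(T_{base}, e)$ with an
exact inner search over $F_{crit}$ (candidate thresholds are the
cumulative forcing values at the observed event days, so the minimum-RMSE
threshold is found without derivatives), and LC by ordinary least
squares with the sign convention enforced.

# Growth factors, seasons and lags

Five season blocks partition the year: Jan–Mar, Apr–May, Jun–Jul,
Aug–Sep, Oct–Dec (the growing season April–September in three two-month
blocks, the dormant season in two three-month blocks). Seven factors are
computed per site, calendar year and season: mean temperature, actual
transpiration sum, climatic water balance (precipitation − actual
transpiration), transpiration deficit sum (potential − actual), mean
soil moisture, and days with REW < 0.4 and < 0.7.

Ring formation is assumed complete by the end of September, so the
current growth year (`act`) uses only the four seasons through
September; the previous (`-1`) and second-previous (`-2`) calendar years
contribute all five seasons, giving 14 legal (season, lag) keys and
4×7 + 2×5×7 = 98 candidate series per site. Lagged values are exact
copies of the earlier calendar year's factors, and the first two years
of a series emit no growth-year rows.

Standardization is z-scoring per (factor, season, lag) stratum, pooling
sites and years over a historical reference window. Pooling preserves
between-site contrasts (which the site random intercept later absorbs),
and the stored moments are **frozen**: scenario years are standardized
against the historical baseline, so projected anomalies are measured in
historical standard deviations and appending future years never changes
historical z-scores. Constant strata (e.g. winter transpiration under a
dormant-season gate of zero) are flagged, set to zero and excluded from
modelling.

# Sensitivity modelling

Screening correlates the site-year mean residual with each of the 98
standardized factor series (Pearson r). To avoid collinearity among the
six water-related factors, preselection keeps, per (season, lag) key,
the water factor with the largest |r| plus mean temperature — at most 28
candidates. Ties resolve by the canonical factor order, making the
choice deterministic.

The sensitivity model is a linear mixed-effects regression of residuals
(individual tree-years by default; site-year means optionally) on the
candidate factors with a random intercept per site, fitted with `nlme`.
ML likelihoods are used for every AIC comparison; the reported estimates
come from a REML refit. Species observed at a single site fall back to
ordinary least squares with a note, and singular random-intercept fits
are refitted without the random effect and flagged. Wald t-table
p-values are reported.

Backward elimination removes, at each step, the single term whose
removal lowers the ML AIC most, stopping when no removal lowers it; the
intercept is never removed and ties resolve by candidate order. Because
a scan over ~28 candidates requires hundreds of ML fits, the scan uses
an exact profiled-likelihood evaluation of the random-intercept model:
for a given variance ratio the GLS problem reduces to OLS on partially
group-demeaned cross-products, and the profile is optimized in one
dimension. Its likelihood agrees with `nlme`/`lme4` to optimizer
tolerance (asserted in the test suite); the retained model is refitted
with `nlme` for reporting.

Marginal and conditional $r^2$ follow the variance-decomposition
convention: fixed-effect variance over total (fixed + site + residual),
and fixed plus site over total; single-site models report conditional
$r^2$ as missing.

# Scenarios and projection

The looped baseline replays the source window (default
2001-01-01–2020-12-31, exactly 7305 days) in order, cycling, with dates
relabelled to the projection calendar — a pure index cycling, so the
first projection day always carries the first source day's weather and
any source-length block of the output equals the source block. Scenario
modifiers are seasonal end-of-century endpoints ramped linearly from the
projection start: the packaged high-emission pathway adds +4&nbsp;°C in
winter and +3&nbsp;°C in summer by 2100 and multiplies winter
precipitation by 1.20 and summer by 1.05; the moderate pathway is half
as strong. Offsets are added to daily minimum and maximum temperature
(the mean is recomputed); multipliers scale daily precipitation;
humidity, wind and radiation are unchanged.

Projection is population-level: predicted residual per site and year is
the intercept plus the sum of retained estimates times the scenario's
standardized factors, with random intercepts set to zero, averaged over
sites. Period summaries use 20-year blocks anchored at 2001 (so
2081–2100 is a block); deltas are scenario-minus-baseline block means,
and the baseline's delta against itself is identically zero.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated — a mid-latitude (48.12° N), beech-dominated landscape:

* **Temperature**: a sinusoid peaking at day-of-year 200 (annual mean
  9.5&nbsp;°C, amplitude 10&nbsp;°C) plus iid Gaussian daily noise
  (sd 3&nbsp;°C); tmin/tmax at ±5&nbsp;°C around the mean.
* **Precipitation**: per-season Bernoulli wet days (p ≈ 0.35–0.40) with
  Gamma amounts (shape 0.8, scale 7&nbsp;mm), ≈ 700&nbsp;mm/yr.
* **Sunshine fraction**: Beta-distributed, lower on wet days, which
  exercises the radiation-estimation path; humidity and wind are mildly
  noisy around 0.75 and 2.5&nbsp;m/s.
* **Soil-moisture observations**: the water-balance trajectory under
  known parameters plus clipped Gaussian noise.
* **Rings**: age-curve value at each tree's cambial age (initial ages
  uniform over 20–120 years) plus a linear combination of standardized
  growth factors under known coefficients, a site random intercept and
  iid noise; widths below 0.01&nbsp;mm are floored and flagged. Planted
  coefficient magnitudes (±0.05–0.10&nbsp;mm per SD), site-intercept sd
  0.15&nbsp;mm and residual sd 0.30&nbsp;mm match the magnitudes typical
  of beech climate-growth analyses; 63 sites × 7 trees × 90 growth years
  (1933–2022) reproduce the reference design in the validation suite.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: spatial correlation between
sites; temporal autocorrelation and low-frequency (interannual to
decadal) climate variability, since daily noise is iid, which makes
seasonal means less variable between years than in real climate and
hence makes *standardized* scenario anomalies (and projected growth
deltas) larger than a real record would give; measurement and
cross-dating error in ring series; species mixtures; and non-linear or
threshold growth responses — the ring generator is linear in the
factors by construction, matching the model being validated rather than
testing its adequacy on real trees.

# Validation design and problem sizes

The test suite validates each operation against independent oracles
(minute-stepping solar geometry, a literal FAO-56 transcription, a
tilted-plane incidence-angle expansion, permutation nulls, closed
forms) and the pipeline end to end: with planted coefficients
{+0.09 soil moisture Jun–Jul, −0.10 temperature Jun–Jul, −0.05 stress
days Aug–Sep lag-1} at 63 sites × 90 years × 7 trees, backward
elimination retains all planted predictors in ≥ 80&nbsp;% of 50
replicates and the full-model estimates fall within 2 standard errors of
truth in ≥ 90&nbsp;% of term-replicates; under a pure-noise response the
per-term false-selection rate stays near AIC's nominal keep probability
($P(\chi^2_1 > 2) \approx 0.16$, somewhat inflated by the water-slot
preselection). These simulation sizes keep the whole suite within a few
minutes on one core while leaving the recovery statistics well away from
their thresholds. The recovery experiment uses site-year mean residuals
as the response; tree-level response is the package default and gives
the same retained models at higher cost.

`scripts/acceptance.R` re-runs a scaled version of the whole chain
(8 sites, history 1961–2024, three scenarios to 2100) from a single
seed and writes the computed quantities as JSON.

# Known limitations

* The single-bucket store has no layers, groundwater or lateral flow,
  and one beech parameterization is applied to all sites.
* The leaf-on gate is binary; no chilling requirement, no species other
  than the beech-type phenology.
* Intercepted water is not returned to the climatic water balance
  (gross precipitation is used in the difference).
* Lag factors are exact copies, so the first two years of every series
  are lost to the lag structure.
* Scenario ramps are linear; no stochastic downscaling or bias
  correction.
* Projected deltas inherit the generator's understated interannual
  variance (see above) and should be read as mechanism demonstrations,
  not calibrated forecasts.
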