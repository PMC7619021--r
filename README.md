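# ringclim

Dendroclimatic water-balance modelling and climate–growth projection for
temperate forest stands.

## The problem

How will the radial growth of long-established tree species respond to a
warming, and seasonally drier, climate? Tree-ring widths integrate two
signals: a deterministic decline with cambial age, and the year-to-year
imprint of weather and soil water. `ringclim` is for forest ecologists
and dendroclimatologists who want to separate those signals, quantify a
species' climate sensitivity with mixed-effects models, and project
growth under climate scenarios — with every stage testable against
synthetic data of known structure.

## The models at its core

**Age detrending.** Expected ring width at cambial age *a* is

    w_age(a) = p_n/a + p_s + w_min − 10·k·ln(1 + exp(0.1·(p_m − a))),
    k = (w_min − w_50)/(p_m − 50)

— a hyperbolic juvenile decline with a softplus-smoothed transition to a
plateau at `p_s + w_min`. The residual `w_res = w_obs − w_age` is the
climate signal. `w_min` (the assumed minimum ring width) is fixed, not
fitted; the remaining parameters are estimated by nonlinear least
squares on the per-age mean series assembled across trees.

**Water balance.** A daily single-bucket model driven by FAO-56
Penman–Monteith reference evapotranspiration (with Ångström–Prescott
radiation from sunshine fraction and slope/aspect correction of the
direct beam). Relative extractable water
`REW = (θ − θ_wp)/(θ_hc − θ_wp)` rescales soil moisture to 0 at the
wilting point and 1 at holding capacity; transpiration is reduced
linearly below REW = 0.4 (severe water deficit; 0.7 marks mild
deficit). The daily mass balance closes to numerical precision.

**Growth factors.** Seven seasonal summaries (mean temperature,
transpiration sum, climatic water balance, transpiration deficit, mean
soil moisture, stress-day counts below REW 0.4 and 0.7) over five season
blocks (Jan–Mar, Apr–May, Jun–Jul, Aug–Sep, Oct–Dec) and three lags
(current growth year through September, previous year, year before
that), z-scored per stratum with frozen historical moments.

**Sensitivity and projection.** Ring-width residuals are regressed on
preselected standardized factors (one water factor plus temperature per
season/lag) in a linear mixed model with a site random intercept
(`nlme`), simplified by backward AIC elimination, and driven with
scenario factors — a looped 2001–2020 baseline vs. RCP-style seasonal
delta-change scenarios — to 2100; results are summarized as 20-year
period deltas against the baseline.

## A worked example

Generate four sites of synthetic weather, run the water balance, build
standardized growth factors, plant a known growth signal in synthetic
rings, and recover it:

```r
library(ringclim)

sites <- sprintf("S%02d", 1:4)
raw <- do.call(rbind, lapply(seq_along(sites), function(i) {
  w  <- generate_weather(weather_config(site_id = sites[i],
                                        start_year = 1960, end_year = 2000,
                                        seed = 100 + i))
  wb <- run_water_balance(w, soil_params(), site_physio(sites[i]))
  daily <- cbind(w[, c("date", "tmean", "precip")],
                 wb[, c("t_act", "t_pot", "theta", "rew")])
  build_growth_factors(daily, sites[i])
}))
lag <- attach_lags(raw)
std <- standardize_factors(lag, reference = c(1962, 2000))

# rings: age curve + planted sensitivities + site effects + noise
ap   <- age_curve_params(2.3, 0, 1.7, 0.9, 218.5, species = "Fagus sylvatica")
beta <- data.frame(factor = c("mean_soil_moisture", "mean_temp"),
                   season = "JunJul", lag = "act", beta = c(0.09, -0.10))
rings <- generate_ring_series(ring_truth(ap, beta, n_sites = 4,
                                         trees_per_site = 7, seed = 9),
                              std$records)
resid <- detrend_rings(rings, ap)

cand  <- preselect_candidates(correlation_screen(resid, std$records))
model <- stepwise_aic(fit_sensitivity(resid, std$records, cand,
                                      species = "Fagus sylvatica"))
model
```

```
<sensitivity_model> Fagus sylvatica
  1092 obs, 4 site(s), response = tree
  ML AIC = 470.65 | site sd = 0.011 mm | resid sd = 0.299 mm
  marginal r2 = 0.182, conditional r2 = 0.183
  intercept = -0.0717 mm + 6 term(s):
                          term estimate        p
          mean_temp_AprMay_act  0.01476 1.09e-01
 mean_soil_moisture_JunJul_act  0.08938 1.39e-21
          mean_temp_JunJul_act -0.10214 1.17e-27
      transp_deficit_JunJul_m1  0.01751 5.90e-02
           mean_temp_JanMar_m2  0.01277 1.66e-01
           mean_temp_AugSep_m2  0.01487 1.13e-01
```

The two planted coefficients are recovered (0.089 vs. 0.09 for June–July
soil moisture, −0.102 vs. −0.10 for June–July temperature, both with
vanishing p-values); the remaining weakly supported terms are the
expected AIC false inclusions. Estimates are in mm of ring width per
standard deviation of the factor. The water balance itself produces
plausible beech-stand numbers under the default synthetic climate — for
a single site, 1990–2022:

```
annual actual transpiration: 382 mm; days REW<0.4: 66
```

Projection then drives the retained model with scenario factors
standardized against the frozen historical moments
(`project_growth()`, `period_summary()`); see the methods vignette
(`vignettes/ringclim-methods.Rmd`) for the full model description.

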