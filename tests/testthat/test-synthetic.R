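# Synthetic-data generators: determinism, degenerate limits, marginals
# and ground-truth structure.

test_that("weather generation is reproducible and obeys invariants", {
  cfg <- weather_config(start_year = 2000, end_year = 2001, seed = 1)
  a <- generate_weather(cfg)
  b <- generate_weather(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 731) # 2000 is a leap year
  expect_true(all(a$tmin <= a$tmean & a$tmean <= a$tmax))
  expect_true(all(a$precip >= 0))
  expect_true(all(a$rh >= 0 & a$rh <= 1))
  expect_true(all(a$sunshine_frac >= 0 & a$sunshine_frac <= 1))
  expect_true(all(is.finite(as.matrix(a[, -1]))))
  expect_error(weather_config(start_year = 2005, end_year = 2000),
               "end_year")
})

test_that("noise-free configuration collapses to the deterministic cycle", {
  cfg <- weather_config(start_year = 2000, end_year = 2000,
                        temp_seasonal_amplitude = 0, temp_daily_sd = 0,
                        temp_mean_annual = 7.5, seed = 2)
  w <- generate_weather(cfg)
  expect_true(all(w$tmean == 7.5))
  expect_true(all(w$tmax == 12.5 & w$tmin == 2.5))
})

test_that("zero wet-day probability yields a dry year", {
  cfg <- weather_config(start_year = 2000, end_year = 2001,
                        precip_wet_prob_by_season =
                          c(JanMar = 0, AprMay = 0, JunJul = 0,
                            AugSep = 0, OctDec = 0), seed = 3)
  expect_true(all(generate_weather(cfg)$precip == 0))
})

test_that("wet days are duller than dry days", {
  w <- generate_weather(weather_config(start_year = 1990, end_year = 2009,
                                       seed = 4))
  expect_lt(mean(w$sunshine_frac[w$precip > 0]),
            mean(w$sunshine_frac[w$precip == 0]))
})

test_that("temperature marginal matches the configuration", {
  cfg <- weather_config(start_year = 1980, end_year = 2011,
                        temp_mean_annual = 9.5, seed = 6)
  w <- generate_weather(cfg)
  se <- sd(w$tmean) / sqrt(nrow(w))
  # 3 SE band plus the small bias from unequal season lengths
  expect_lt(abs(mean(w$tmean) - 9.5), 3 * se + 0.15)
})

test_that("soil-moisture observations reduce to the simulation at zero noise", {
  w <- generate_weather(weather_config(start_year = 2000, end_year = 2001,
                                       seed = 7))
  s <- soil_params(); p <- site_physio("A")
  obs0 <- generate_soil_moisture_obs(w, s, p, noise_sd = 0)
  sim <- run_water_balance(w, s, p)
  expect_identical(obs0$theta, sim$theta)
  o1 <- generate_soil_moisture_obs(w, s, p, noise_sd = 0.02, seed = 9)
  o2 <- generate_soil_moisture_obs(w, s, p, noise_sd = 0.02, seed = 9)
  expect_identical(o1, o2)
  expect_false(identical(o1$theta, sim$theta))
  expect_true(all(o1$theta >= 0 & o1$theta <= 1))
  expect_error(generate_soil_moisture_obs(w, s, p, noise_sd = -0.1),
               "noise_sd")
})

test_that("ring generation reproduces the pure age curve when silent", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = character(), season = character(),
                                 lag = character(), beta = numeric()),
                   site_intercept_sd = 0, residual_sd = 0,
                   n_sites = 4, trees_per_site = 7, seed = 10)
  rings <- generate_ring_series(tr, std$records)
  expect_equal(length(unique(rings$tree_id)), 28L) # 4 sites x 7 trees
  d <- detrend_rings(rings, p)
  expect_lt(max(abs(d$w_res)), 1e-12)
  # determinism
  rings2 <- generate_ring_series(tr, std$records)
  expect_identical(rings, rings2)
})

test_that("a missing factor key is reported by name", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = "mean_temp", season = "JunJul",
                                 lag = "act", beta = 0.1),
                   n_sites = 4, trees_per_site = 2, seed = 11)
  crippled <- std$records[!(std$records$factor == "mean_temp" &
                              std$records$season == "JunJul" &
                              std$records$lag == "act"), ]
  expect_error(generate_ring_series(tr, crippled),
               "mean_temp, JunJul, act")
  expect_error(ring_truth(p, data.frame(factor = "mean_temp",
                                        season = "OctDec", lag = "act",
                                        beta = 0.1)),
               "illegal")
})

test_that("a planted positive coefficient leaves a positive residual signal", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  x <- std$records[std$records$factor == "mean_soil_moisture" &
                     std$records$season == "JunJul" &
                     std$records$lag == "act", ]
  xkey <- paste(x$site_id, x$growth_year)
  set.seed(21)
  r_by_rep <- replicate(100, {
    tr <- ring_truth(p, data.frame(factor = "mean_soil_moisture",
                                   season = "JunJul", lag = "act",
                                   beta = 0.1),
                     site_intercept_sd = 0.1, residual_sd = 0.3,
                     n_sites = 4, trees_per_site = 7,
                     seed = sample.int(1e6, 1))
    rings <- generate_ring_series(tr, std$records)
    d <- detrend_rings(rings, p)
    m <- aggregate(w_res ~ site_id + year, data = d, FUN = mean)
    cor(m$w_res, x$std_value[match(paste(m$site_id, m$year), xkey)])
  })
  expect_gt(mean(r_by_rep), 0.15)
  expect_gt(mean(r_by_rep > 0), 0.95)
})

test_that("negative widths are floored at 0.01 mm and flagged", {
  std <- fx_factors()
  tiny <- age_curve_params(p_n = 0.1, p_s = 0, w_50 = 0.02, w_min = 0.02,
                           p_m = 100)
  tr <- ring_truth(tiny, data.frame(factor = character(),
                                    season = character(),
                                    lag = character(), beta = numeric()),
                   site_intercept_sd = 0, residual_sd = 0.5,
                   n_sites = 2, trees_per_site = 2, seed = 12)
  expect_message(rings <- generate_ring_series(tr, std$records), "floored")
  expect_true(all(rings$w_obs >= 0.01))
  expect_gt(attr(rings, "n_floored"), 0)
  expect_true(all(rings$w_obs[rings$floored] == 0.01))
  expect_equal(sum(rings$floored), attr(rings, "n_floored"))
})
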