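# Water balance: REW, Penman-Monteith demand, the daily step, mass
# conservation, stress-day counts and soil calibration.

test_that("REW is the clamped linear rescaling between wp and hc", {
  s <- soil_params(theta_wp = 0.10, theta_hc = 0.30)
  expect_equal(compute_rew(0.10, s), 0)
  expect_equal(compute_rew(0.30, s), 1)
  expect_equal(compute_rew(0.20, s), 0.5)
  expect_equal(compute_rew(0.05, s), 0) # clamped below wilting point
  expect_equal(compute_rew(0.40, s), 1) # clamped above holding capacity
  expect_error(soil_params(theta_wp = 0.3, theta_hc = 0.3), "degenerate")
})

test_that("stress-day counts honour thresholds and ordering", {
  rew <- c(0.3, 0.5, 0.8)
  expect_equal(count_stress_days(rew, 0.4), 1)
  expect_equal(count_stress_days(rew, 0.7), 2)
  expect_equal(count_stress_days(rep(1, 50), 0.4), 0)
  expect_equal(count_stress_days(rep(1, 50), 0.7), 0)
  # severe days are a subset of mild days on any window
  set.seed(7)
  for (i in 1:20) {
    r <- runif(100)
    expect_lte(count_stress_days(r, 0.4), count_stress_days(r, 0.7))
    expect_lte(count_stress_days(r, 0.7), length(r))
  }
  # non-strict counting includes the boundary
  expect_equal(count_stress_days(c(0.4, 0.5), 0.4, strict = FALSE), 1)
  expect_equal(count_stress_days(c(0.4, 0.5), 0.4, strict = TRUE), 0)
})

# independent, literal FAO-56 transcription used as an oracle
fao56_oracle <- function(tmin, tmax, rh, rs, u2, z, lat, doy) {
  tmean <- (tmin + tmax) / 2
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (e0(tmin) + e0(tmax)) / 2
  ea <- rh * es
  slope <- 4098 * e0(tmean) / (tmean + 237.3)^2
  p <- 101.3 * ((293 - 0.0065 * z) / 293)^5.26
  gam <- 0.000665 * p
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dd <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(-tan(phi) * tan(dd))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dd) + cos(phi) * cos(dd) * sin(ws))
  rso <- (0.75 + 2e-5 * z) * ra
  rns <- 0.77 * rs
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * rs / rso - 0.35)
  rn <- rns - rnl
  (0.408 * slope * rn + gam * 900 / (tmean + 273) * u2 * (es - ea)) /
    (slope + gam * (1 + 0.34 * u2))
}

test_that("Penman-Monteith matches an independent FAO-56 transcription", {
  # standard mid-latitude summer day
  got <- penman_monteith_et0(tmin = 12.3, tmax = 21.5, rh = 0.68,
                             rad = 22.07, wind = 2.08, elevation = 100,
                             latitude = 50.8, date = 187)
  want <- fao56_oracle(12.3, 21.5, 0.68, 22.07, 2.08, 100, 50.8, 187)
  expect_equal(got, want, tolerance = 1e-3)
  expect_gt(got, 2); expect_lt(got, 6) # plausible summer magnitude
})

test_that("evaporative demand vanishes without energy or dryness", {
  et0 <- penman_monteith_et0(tmin = 10, tmax = 10, rh = 1, rad = 0,
                             wind = 0, elevation = 500, latitude = 48,
                             date = 1)
  expect_lte(et0, 0.05)
  # doubling VPD (halving humidity) at fixed radiation raises demand
  lo <- penman_monteith_et0(15, 25, 0.9, 20, 2, 500, 48, 172)
  hi <- penman_monteith_et0(15, 25, 0.45, 20, 2, 500, 48, 172)
  expect_gt(hi, lo)
  expect_error(penman_monteith_et0(15, 25, 1.2, 20, 2, 500, 48, 172),
               "rh")
})

test_that("the daily step shuts, saturates and transitions correctly", {
  s <- soil_params(theta_wp = 0.1, theta_hc = 0.3, root_depth = 500)
  # dry soil: REW = 0 shuts transpiration, store untouched
  d <- wb_step(precip = 0, tmean = 15, et0 = 5, theta = 0.1,
               snowpack = 0, soil = s)
  expect_equal(d$t_act, 0)
  expect_equal(d$theta, 0.1)
  expect_gt(d$t_deficit, 0)
  # saturated soil: all throughfall drains
  d2 <- wb_step(precip = 40, tmean = 15, et0 = 0, theta = 0.3,
                snowpack = 0, soil = s)
  expect_equal(d2$drainage, 40 * (1 - s$interception_frac))
  expect_equal(d2$theta, 0.3)
  # at the critical REW the reduction function reaches 1
  theta_crit <- s$theta_wp + s$rew_crit * (s$theta_hc - s$theta_wp)
  d3 <- wb_step(precip = 0, tmean = 15, et0 = 3, theta = theta_crit,
                snowpack = 0, soil = s)
  expect_equal(d3$t_act, d3$t_pot)
  # below freezing precipitation accumulates as snow
  d4 <- wb_step(precip = 10, tmean = -5, et0 = 0.2, theta = 0.2,
                snowpack = 0, soil = s)
  expect_equal(d4$snowpack, 10)
  expect_equal(d4$rain, 0)
})

test_that("mass balance closes to 1e-9 mm over random forcing", {
  s <- soil_params(theta_wp = 0.08, theta_hc = 0.33, root_depth = 700)
  f <- fx_random_forcing(10000, seed = 3)
  theta <- 0.2; snow <- 0
  worst <- 0; t_act_ok <- TRUE
  for (i in seq_len(10000)) {
    d <- wb_step(f$precip[i], f$tmean[i], f$et0[i], theta, snow, s,
                 in_leaf = f$in_leaf[i])
    d_storage <- (d$theta - theta) * s$root_depth
    err <- abs(d$rain + d$melt - d$interception - d$t_act - d$drainage -
                 d_storage)
    worst <- max(worst, err)
    t_act_ok <- t_act_ok && d$t_act >= 0 && d$t_act <= d$t_pot + 1e-12
    theta <- d$theta; snow <- d$snowpack
  }
  expect_lt(worst, 1e-9)
  expect_true(t_act_ok)
})

test_that("the vectorized runner reproduces sequential single steps", {
  w <- generate_weather(weather_config(start_year = 1999, end_year = 2000,
                                       seed = 21))
  s <- soil_params(); p <- site_physio("X")
  run <- run_water_balance(w, s, p)
  theta <- s$theta_hc; snow <- 0
  for (i in seq_len(nrow(w))) {
    d <- wb_step(w$precip[i], w$tmean[i], run$et0[i], theta, snow, s,
                 in_leaf = run$in_leaf[i])
    theta <- d$theta; snow <- d$snowpack
  }
  expect_equal(run$theta[nrow(w)], theta, tolerance = 1e-12)
  # state invariants over the whole run
  expect_true(all(run$theta >= s$theta_wp - 1e-12))
  expect_true(all(run$theta <= s$theta_hc + 1e-12))
  expect_true(all(run$rew >= 0 & run$rew <= 1))
  expect_true(all(run$t_deficit >= -1e-12))
})

test_that("warming the whole series never lowers annual demand", {
  w <- generate_weather(weather_config(start_year = 2000, end_year = 2002,
                                       seed = 31))
  s <- soil_params(); p <- site_physio("X")
  base <- run_water_balance(w, s, p)
  warm <- w
  warm$tmin <- warm$tmin + 3; warm$tmax <- warm$tmax + 3
  warm$tmean <- warm$tmean + 3
  up <- run_water_balance(warm, s, p)
  expect_gte(sum(up$t_pot), sum(base$t_pot))
})

test_that("calibration recovers parameters from noise-free observations", {
  w <- generate_weather(weather_config(start_year = 1999, end_year = 2001,
                                       seed = 41))
  p <- site_physio("CAL")
  truth <- soil_params(theta_wp = 0.12, theta_hc = 0.30, root_depth = 650)
  obs <- generate_soil_moisture_obs(w, truth, p, noise_sd = 0)
  fit <- calibrate_wbm(w, obs, p, n_starts = 6, seed = 2)
  sim <- run_water_balance(w, fit$soil, p)
  expect_lt(sqrt(mean((sim$theta - obs$theta)^2)), 1e-5)
  expect_lt(abs(fit$soil$theta_hc - 0.30), 0.01)
})

test_that("bounds that exclude the truth give a flagged boundary fit", {
  w <- generate_weather(weather_config(start_year = 2000, end_year = 2001,
                                       seed = 43))
  p <- site_physio("CAL")
  truth <- soil_params(theta_wp = 0.12, theta_hc = 0.30, root_depth = 650)
  obs <- generate_soil_moisture_obs(w, truth, p, noise_sd = 0)
  expect_warning(
    fit <- calibrate_wbm(w, obs, p,
                         lower = c(theta_wp = 0.02, theta_hc = 0.35,
                                   root_depth = 300),
                         upper = c(theta_wp = 0.10, theta_hc = 0.45,
                                   root_depth = 1200),
                         n_starts = 4, seed = 2),
    "bound")
  expect_true(fit$at_bounds)
})
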