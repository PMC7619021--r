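# Synthetic-data generators with known ground truth: daily weather,
# soil-moisture "observations", phenology events and ring-width series.
# These define the study conditions under which the pipeline is validated:
# a mid-latitude, beech-dominated landscape with seasonally cyclic
# temperature, Bernoulli-Gamma precipitation and rings composed of a known
# age curve, a linear combination of standardized growth factors, a site
# random intercept and iid noise.

#' Configuration of the synthetic daily-weather generator
#'
#' Temperature is a sinusoid peaking at day-of-year 200 plus iid Gaussian
#' noise; tmin/tmax sit a fixed half-range below/above the mean.
#' Precipitation occurrence is Bernoulli per season, amounts Gamma.
#' Sunshine fraction is Beta-distributed and lower on wet days; humidity
#' and wind are mildly noisy around their means.
#'
#' @param site_id site identifier.
#' @param latitude degrees north.
#' @param start_year,end_year calendar years covered (inclusive).
#' @param temp_mean_annual annual mean temperature, deg C.
#' @param temp_seasonal_amplitude half peak-to-trough seasonal swing, deg C.
#' @param temp_daily_sd sd of daily temperature noise, deg C.
#' @param temp_half_range (tmax - tmin)/2, deg C.
#' @param precip_wet_prob_by_season named per-season wet-day probability.
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters of wet-day
#'   amounts (mm).
#' @param rh_mean mean relative humidity, fraction.
#' @param wind_mean mean wind speed, m/s.
#' @param sunshine_dry,sunshine_wet mean sunshine fraction on dry/wet days.
#' @param seed integer RNG seed.
#' @return an object of class \code{weather_config}.
#' @export
weather_config <- function(site_id = "S01", latitude = 48.12,
                           start_year = 1931, end_year = 2022,
                           temp_mean_annual = 9.5,
                           temp_seasonal_amplitude = 10,
                           temp_daily_sd = 3, temp_half_range = 5,
                           precip_wet_prob_by_season =
                             c(JanMar = 0.35, AprMay = 0.38, JunJul = 0.40,
                               AugSep = 0.36, OctDec = 0.35),
                           precip_gamma_shape = 0.8,
                           precip_gamma_scale = 7,
                           rh_mean = 0.75, wind_mean = 2.5,
                           sunshine_dry = 0.60, sunshine_wet = 0.20,
                           seed = 1L) {
  if (end_year < start_year) stop("end_year must be >= start_year")
  stopifnot(all(precip_wet_prob_by_season >= 0 &
                  precip_wet_prob_by_season <= 1),
            setequal(names(precip_wet_prob_by_season), season_levels()),
            precip_gamma_shape > 0, precip_gamma_scale > 0,
            rh_mean >= 0, rh_mean <= 1, temp_daily_sd >= 0,
            temp_seasonal_amplitude >= 0, temp_half_range >= 0)
  structure(list(site_id = site_id, latitude = latitude,
                 start_year = start_year, end_year = end_year,
                 temp_mean_annual = temp_mean_annual,
                 temp_seasonal_amplitude = temp_seasonal_amplitude,
                 temp_daily_sd = temp_daily_sd,
                 temp_half_range = temp_half_range,
                 precip_wet_prob_by_season =
                   precip_wet_prob_by_season[season_levels()],
                 precip_gamma_shape = precip_gamma_shape,
                 precip_gamma_scale = precip_gamma_scale,
                 rh_mean = rh_mean, wind_mean = wind_mean,
                 sunshine_dry = sunshine_dry, sunshine_wet = sunshine_wet,
                 seed = as.integer(seed)),
            class = "weather_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic daily weather series
#'
#' @param cfg a [weather_config()].
#' @return daily weather table: date, tmin, tmax, tmean, precip, rh,
#'   sunshine_frac, wind.
#' @export
generate_weather <- function(cfg) {
  stopifnot(inherits(cfg, "weather_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$end_year)), by = "day")
  n <- length(dates)
  doy <- doy_of(dates)
  season <- season_of_month(dates)
  with_seed(cfg$seed, {
    tmean <- cfg$temp_mean_annual +
      cfg$temp_seasonal_amplitude * cos(2 * pi * (doy - 200) / 365.25) +
      rnorm(n, 0, cfg$temp_daily_sd)
    wet_p <- cfg$precip_wet_prob_by_season[season]
    wet <- rbinom(n, 1, wet_p) == 1
    precip <- numeric(n)
    precip[wet] <- rgamma(sum(wet), shape = cfg$precip_gamma_shape,
                          scale = cfg$precip_gamma_scale)
    rh <- pmin(1, pmax(0.05, rnorm(n, cfg$rh_mean, 0.07)))
    conc <- 6
    sun_mean <- ifelse(wet, cfg$sunshine_wet, cfg$sunshine_dry)
    sun_mean <- pmin(0.98, pmax(0.02, sun_mean))
    sunshine <- rbeta(n, sun_mean * conc, (1 - sun_mean) * conc)
    wind <- pmax(0.1, rnorm(n, cfg$wind_mean, 0.3 * cfg$wind_mean))
    data.frame(date = dates,
               tmin = tmean - cfg$temp_half_range,
               tmax = tmean + cfg$temp_half_range,
               tmean = tmean, precip = precip, rh = rh,
               sunshine_frac = sunshine, wind = wind)
  })
}

#' Generate noisy soil-moisture "observations"
#'
#' Runs the water-balance model under known (true) soil parameters and adds
#' iid Gaussian measurement noise, clipped to the physical range [0, 1] —
#' the calibration target a field soil-moisture probe would provide.
#'
#' @param weather daily weather series.
#' @param soil true [soil_params()].
#' @param physio [site_physio()].
#' @param noise_sd sd of the measurement noise, volumetric fraction.
#' @param seed RNG seed.
#' @param leaf passed to [run_water_balance()].
#' @return data frame: date, theta.
#' @export
generate_soil_moisture_obs <- function(weather, soil, physio,
                                       noise_sd = 0.02, seed = 1,
                                       leaf = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sim <- run_water_balance(weather, soil, physio, leaf = leaf)
  theta <- sim$theta
  if (noise_sd > 0) {
    theta <- with_seed(seed, theta + rnorm(length(theta), 0, noise_sd))
    theta <- pmin(1, pmax(0, theta))
  }
  data.frame(date = sim$date, theta = theta)
}

#' Ground truth of the synthetic ring-width generator
#'
#' @param age_params an [age_curve_params()].
#' @param beta data frame (factor, season, lag, beta) of true
#'   standardized-factor coefficients, mm per SD unit.
#' @param site_intercept_sd sd of the site random intercept, mm.
#' @param residual_sd sd of the tree-year residual noise, mm.
#' @param n_sites,trees_per_site design size.
#' @param age_at_start_range cambial age at the first generated year is
#'   drawn uniformly from this range per tree.
#' @param species species label.
#' @param seed RNG seed.
#' @return an object of class \code{ring_truth}.
#' @export
ring_truth <- function(age_params, beta,
                       site_intercept_sd = 0.15, residual_sd = 0.30,
                       n_sites = 4, trees_per_site = 7,
                       age_at_start_range = c(20, 120),
                       species = "Fagus sylvatica", seed = 1L) {
  stopifnot(inherits(age_params, "age_curve_params"),
            trees_per_site > 0, n_sites > 0,
            residual_sd >= 0, site_intercept_sd >= 0)
  if (nrow(beta) > 0) {
    stopifnot(all(c("factor", "season", "lag", "beta") %in% names(beta)))
    bad <- beta$season == "OctDec" & beta$lag == "act"
    if (any(bad)) stop("beta contains the illegal (OctDec, act) key")
  }
  structure(list(age_params = age_params, beta = beta,
                 site_intercept_sd = site_intercept_sd,
                 residual_sd = residual_sd, n_sites = n_sites,
                 trees_per_site = trees_per_site,
                 age_at_start_range = age_at_start_range,
                 species = species, seed = as.integer(seed)),
            class = "ring_truth")
}

#' Generate ring-width series from known structure
#'
#' Observed width per tree and year is the age-curve value at the tree's
#' cambial age, plus the linear combination of standardized growth factors
#' under the true coefficients, plus a site random intercept and iid
#' noise. Widths below 0.01 mm are floored and flagged.
#'
#' @param truth a [ring_truth()].
#' @param factors standardized factor records covering every
#'   (site, growth year) to generate; sites are taken from this table
#'   (first \code{n_sites} in sort order).
#' @param years growth years to generate (default: all in \code{factors}).
#' @return data frame: species, site_id, tree_id, year, age, w_obs,
#'   floored; attributes \code{site_effects} (named vector) and
#'   \code{n_floored}.
#' @export
generate_ring_series <- function(truth, factors, years = NULL) {
  stopifnot(inherits(truth, "ring_truth"))
  sites <- sort(unique(factors$site_id))
  if (length(sites) < truth$n_sites) {
    stop("factors cover ", length(sites), " site(s) but truth needs ",
         truth$n_sites)
  }
  sites <- sites[seq_len(truth$n_sites)]
  years <- years %||% sort(unique(factors$growth_year))

  # per-site linear predictor from the true betas
  signal <- matrix(0, nrow = length(years), ncol = length(sites),
                   dimnames = list(years, sites))
  if (nrow(truth$beta) > 0) {
    grid_key <- paste(rep(sites, each = length(years)),
                      rep(years, times = length(sites)), sep = "\r")
    for (j in seq_len(nrow(truth$beta))) {
      b <- truth$beta[j, ]
      sub <- factors[factors$factor == b$factor &
                       factors$season == b$season &
                       factors$lag == b$lag, , drop = FALSE]
      i <- match(grid_key, paste(sub$site_id, sub$growth_year, sep = "\r"))
      if (anyNA(i)) {
        miss <- grid_key[is.na(i)][1]
        stop("factors miss key (", b$factor, ", ", b$season, ", ",
             b$lag, ") for site/year ", gsub("\r", " ", miss))
      }
      signal <- signal + b$beta *
        matrix(sub$std_value[i], nrow = length(years))
    }
  }

  with_seed(truth$seed, {
    b_site <- rnorm(length(sites), 0, truth$site_intercept_sd)
    names(b_site) <- sites
    n_tree <- length(sites) * truth$trees_per_site
    n_yr <- length(years)
    tree_site <- rep(sites, each = truth$trees_per_site)
    tree_no <- rep(seq_len(truth$trees_per_site), times = length(sites))
    age_v <- w_v <- numeric(n_tree * n_yr)
    for (k in seq_len(n_tree)) {
      age0 <- round(runif(1, truth$age_at_start_range[1],
                          truth$age_at_start_range[2]))
      age <- age0 + seq_len(n_yr) - 1L
      eps <- rnorm(n_yr, 0, truth$residual_sd)
      idx <- (k - 1L) * n_yr + seq_len(n_yr)
      age_v[idx] <- age
      w_v[idx] <- age_curve(age, truth$age_params) +
        signal[, tree_site[k]] + b_site[tree_site[k]] + eps
    }
    out <- data.frame(
      species = truth$species,
      site_id = rep(tree_site, each = n_yr),
      tree_id = rep(sprintf("%s_T%02d", tree_site, tree_no), each = n_yr),
      year = rep(years, times = n_tree),
      age = as.integer(age_v), w_obs = w_v)
    floored <- out$w_obs < 0.01
    out$w_obs[floored] <- 0.01
    out$floored <- floored
    if (any(floored)) {
      message(sum(floored), " generated width(s) floored at 0.01 mm")
    }
    rownames(out) <- NULL
    attr(out, "site_effects") <- b_site
    attr(out, "n_floored") <- sum(floored)
    out
  })
}
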