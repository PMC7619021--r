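# Daily single-store forest water balance: soil moisture, relative
# extractable water (REW), potential and actual transpiration, drainage and
# a simple degree-day snowpack. One bucket of depth `root_depth` holds
# plant-available water between the wilting point and the water holding
# capacity; transpiration is reduced linearly below a critical REW.

#' Soil and stand parameters of the water-balance model
#'
#' @param theta_wp volumetric soil moisture at the wilting point (REW = 0).
#' @param theta_hc volumetric soil moisture at water holding capacity
#'   (REW = 1); must exceed \code{theta_wp}.
#' @param root_depth effective rooting depth of the profile, mm.
#' @param rew_crit REW below which transpiration is reduced linearly;
#'   0.4 marks the onset of severe water deficit.
#' @param interception_frac fraction of in-leaf rainfall intercepted by the
#'   canopy and evaporated.
#' @param snow_melt_factor degree-day melt factor, mm per deg C per day.
#' @param canopy_coef scaling from reference evapotranspiration to stand
#'   potential transpiration.
#' @param dormant_coef transpiration gate outside the growing season
#'   (0 = none).
#' @return an object of class \code{soil_params}.
#' @export
soil_params <- function(theta_wp = 0.12, theta_hc = 0.32, root_depth = 600,
                        rew_crit = 0.4, interception_frac = 0.15,
                        snow_melt_factor = 3, canopy_coef = 0.8,
                        dormant_coef = 0) {
  assert_scalar_num(theta_wp, "theta_wp", 0, 1)
  assert_scalar_num(theta_hc, "theta_hc", 0, 1)
  if (theta_hc <= theta_wp) {
    stop("degenerate soil: theta_hc must exceed theta_wp")
  }
  assert_scalar_num(root_depth, "root_depth", 1e-6, Inf)
  assert_scalar_num(rew_crit, "rew_crit", 1e-9, 1)
  assert_scalar_num(interception_frac, "interception_frac", 0, 1)
  assert_scalar_num(snow_melt_factor, "snow_melt_factor", 0, Inf)
  structure(list(theta_wp = theta_wp, theta_hc = theta_hc,
                 root_depth = root_depth, rew_crit = rew_crit,
                 interception_frac = interception_frac,
                 snow_melt_factor = snow_melt_factor,
                 canopy_coef = canopy_coef, dormant_coef = dormant_coef),
            class = "soil_params")
}

#' @export
print.soil_params <- function(x, ...) {
  cat("<soil_params>\n")
  cat(sprintf("  theta_wp = %.3f, theta_hc = %.3f, root depth = %.0f mm\n",
              x$theta_wp, x$theta_hc, x$root_depth))
  cat(sprintf("  rew_crit = %.2f, interception = %.2f, melt = %.1f mm/degC/d\n",
              x$rew_crit, x$interception_frac, x$snow_melt_factor))
  invisible(x)
}

#' Site physiography
#'
#' @param site_id site identifier.
#' @param latitude degrees north.
#' @param elevation m a.s.l.
#' @param slope degrees from horizontal, in [0, 90).
#' @param aspect downslope direction, degrees clockwise from north.
#' @return an object of class \code{site_physio}.
#' @export
site_physio <- function(site_id, latitude = 48.12, elevation = 510,
                        slope = 0, aspect = 180) {
  stopifnot(slope >= 0, slope < 90, aspect >= 0, aspect < 360,
            latitude > -90, latitude < 90)
  structure(list(site_id = site_id, latitude = latitude,
                 elevation = elevation, slope = slope, aspect = aspect),
            class = "site_physio")
}

#' Relative extractable water
#'
#' \eqn{REW = (\theta - \theta_{wp}) / (\theta_{hc} - \theta_{wp})},
#' clamped to [0, 1]: 0 at the wilting point, 1 at water holding capacity.
#'
#' @param theta volumetric soil moisture (vectorized).
#' @param soil a [soil_params()].
#' @return REW in [0, 1].
#' @export
compute_rew <- function(theta, soil) {
  stopifnot(inherits(soil, "soil_params"))
  pmin(1, pmax(0, (theta - soil$theta_wp) / (soil$theta_hc - soil$theta_wp)))
}

#' Count water-stress days
#'
#' Number of days on which REW undershoots a threshold; 0.4 marks severe
#' and 0.7 (at least) mild water deficit.
#'
#' @param rew REW series.
#' @param threshold stress threshold in (0, 1).
#' @param strict logical; count \code{rew < threshold} (default) or
#'   \code{rew <= threshold}.
#' @return integer count.
#' @export
count_stress_days <- function(rew, threshold, strict = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  if (strict) sum(rew < threshold) else sum(rew <= threshold)
}

#' One day of the water-balance model
#'
#' Flux order within a day: (1) precipitation falls as snow below 0 deg C,
#' else as rain; (2) degree-day melt releases snowpack; (3) throughfall =
#' rain net of in-leaf interception, plus melt; (4) potential transpiration
#' gates reference evapotranspiration by leaf phenology; (5) actual
#' transpiration is potential times \code{min(1, REW/rew_crit)}, capped by
#' extractable water; (6) the store is updated and (7) water above holding
#' capacity drains. The daily mass balance
#' rain + melt - interception - t_act - drainage = change in stored water
#' closes to numerical precision.
#'
#' @param precip,tmean daily precipitation (mm) and mean temperature (deg C).
#' @param et0 reference evapotranspiration, mm/day.
#' @param theta,snowpack state at start of day: volumetric soil moisture
#'   and snow water equivalent (mm).
#' @param soil a [soil_params()].
#' @param in_leaf logical: within the growing season?
#' @return a one-row data frame: theta, rew, t_pot, t_act, t_deficit,
#'   drainage, snowpack, interception, rain, melt, in_leaf.
#' @export
wb_step <- function(precip, tmean, et0, theta, snowpack, soil,
                    in_leaf = TRUE) {
  stopifnot(inherits(soil, "soil_params"))
  rd <- soil$root_depth
  w0 <- theta * rd

  snow_fall <- if (tmean < 0) precip else 0
  rain <- precip - snow_fall
  snowpack <- snowpack + snow_fall
  melt <- min(snowpack, soil$snow_melt_factor * max(tmean, 0))
  snowpack <- snowpack - melt

  interception <- rain * soil$interception_frac * as.numeric(in_leaf)
  throughfall <- rain - interception + melt

  rew0 <- compute_rew(theta, soil)
  gate <- if (in_leaf) 1 else soil$dormant_coef
  t_pot <- soil$canopy_coef * et0 * gate
  t_act <- t_pot * min(1, rew0 / soil$rew_crit)
  t_act <- min(t_act, max(0, w0 + throughfall - soil$theta_wp * rd))

  w1 <- w0 + throughfall - t_act
  drainage <- max(0, w1 - soil$theta_hc * rd)
  w1 <- w1 - drainage
  theta1 <- w1 / rd

  data.frame(theta = theta1, rew = compute_rew(theta1, soil),
             t_pot = t_pot, t_act = t_act, t_deficit = t_pot - t_act,
             drainage = drainage, snowpack = snowpack,
             interception = interception, rain = rain, melt = melt,
             in_leaf = in_leaf)
}

#' Run the water-balance model over a daily weather series
#'
#' Computes FAO-56 reference evapotranspiration (estimating radiation from
#' sunshine fraction and adjusting for slope/aspect where needed), derives
#' the in-leaf gate from per-year leaf unfolding / coloring days, and
#' integrates the bucket store day by day.
#'
#' @param weather daily weather table (see [validate_weather()]).
#' @param soil a [soil_params()].
#' @param physio a [site_physio()].
#' @param leaf either a logical vector (one per day), a data frame with
#'   columns \code{year}, \code{lu}, \code{lc} (day-of-year bounds of the
#'   leaf-on season per year), or \code{NULL} for the default fixed window
#'   (day 110--290).
#' @param theta_init initial soil moisture (defaults to holding capacity).
#' @return data frame of daily states and fluxes (one row per weather day),
#'   including the driving \code{et0}.
#' @export
run_water_balance <- function(weather, soil, physio, leaf = NULL,
                              theta_init = NULL) {
  stopifnot(inherits(soil, "soil_params"), inherits(physio, "site_physio"))
  weather <- validate_weather(weather)
  n <- nrow(weather)
  rad <- weather$rad
  if (is.null(rad)) {
    rad <- estimate_radiation(weather$sunshine_frac, weather$date,
                              physio$latitude)
  }
  if (physio$slope > 0) {
    rad <- adjust_radiation_for_terrain(rad, weather$date, physio$latitude,
                                        physio$slope, physio$aspect,
                                        sunshine_frac = weather$sunshine_frac)
  }
  et0 <- penman_monteith_et0(weather$tmin, weather$tmax, weather$rh, rad,
                             weather$wind, physio$elevation, physio$latitude,
                             weather$date)
  in_leaf <- leaf_gate(weather$date, leaf, n)

  rd <- soil$root_depth
  wp_mm <- soil$theta_wp * rd
  hc_mm <- soil$theta_hc * rd
  theta <- numeric(n); t_pot_v <- numeric(n); t_act_v <- numeric(n)
  drain_v <- numeric(n); snow_v <- numeric(n); icept_v <- numeric(n)
  rain_v <- numeric(n); melt_v <- numeric(n)

  th <- theta_init %||% soil$theta_hc
  sp <- 0
  precip <- weather$precip; tmean <- weather$tmean
  mf <- soil$snow_melt_factor; ifr <- soil$interception_frac
  cc <- soil$canopy_coef; dc <- soil$dormant_coef; rc <- soil$rew_crit
  span <- soil$theta_hc - soil$theta_wp

  for (i in seq_len(n)) {
    w0 <- th * rd
    if (tmean[i] < 0) { snow_fall <- precip[i]; rain <- 0 }
    else { snow_fall <- 0; rain <- precip[i] }
    sp <- sp + snow_fall
    melt <- min(sp, mf * max(tmean[i], 0))
    sp <- sp - melt
    icept <- rain * ifr * as.numeric(in_leaf[i])
    thr <- rain - icept + melt
    rew0 <- min(1, max(0, (th - soil$theta_wp) / span))
    t_pot <- cc * et0[i] * (if (in_leaf[i]) 1 else dc)
    t_act <- t_pot * min(1, rew0 / rc)
    t_act <- min(t_act, max(0, w0 + thr - wp_mm))
    w1 <- w0 + thr - t_act
    drain <- max(0, w1 - hc_mm)
    w1 <- w1 - drain
    th <- w1 / rd
    theta[i] <- th; t_pot_v[i] <- t_pot; t_act_v[i] <- t_act
    drain_v[i] <- drain; snow_v[i] <- sp; icept_v[i] <- icept
    rain_v[i] <- rain; melt_v[i] <- melt
  }

  data.frame(date = weather$date, theta = theta,
             rew = compute_rew(theta, soil),
             t_pot = t_pot_v, t_act = t_act_v,
             t_deficit = t_pot_v - t_act_v,
             drainage = drain_v, snowpack = snow_v,
             interception = icept_v, rain = rain_v, melt = melt_v,
             in_leaf = in_leaf, et0 = et0)
}

# resolve the leaf-on gate for each day
leaf_gate <- function(date, leaf, n) {
  if (is.null(leaf)) {
    d <- doy_of(date)
    return(d >= 110 & d <= 290)
  }
  if (is.logical(leaf)) {
    stopifnot(length(leaf) == n)
    return(leaf)
  }
  stopifnot(is.data.frame(leaf), all(c("year", "lu", "lc") %in% names(leaf)))
  yr <- year_of(date); d <- doy_of(date)
  i <- match(yr, leaf$year)
  if (anyNA(i)) stop("leaf table misses years: ",
                     paste(unique(yr[is.na(i)]), collapse = ", "))
  d >= leaf$lu[i] & d <= leaf$lc[i]
}

#' Calibrate the water-balance model against observed soil moisture
#'
#' Minimizes the root-mean-square error between simulated and observed
#' volumetric soil moisture over \code{theta_wp}, \code{theta_hc} and
#' \code{root_depth}, by bounded local search (L-BFGS-B) from a fixed-seed
#' Latin-hypercube multistart.
#'
#' @param weather daily weather covering the observation period.
#' @param observed data frame with columns \code{date}, \code{theta}.
#' @param physio a [site_physio()].
#' @param soil template [soil_params()] supplying the non-calibrated
#'   parameters.
#' @param lower,upper named bounds for \code{theta_wp}, \code{theta_hc},
#'   \code{root_depth}.
#' @param leaf passed to [run_water_balance()].
#' @param n_starts number of Latin-hypercube starting points.
#' @param seed RNG seed for the multistart design.
#' @return list with \code{soil} (calibrated [soil_params()]), \code{rmse},
#'   \code{at_bounds} (logical flag) and \code{starts} (per-start results).
#' @export
calibrate_wbm <- function(weather, observed, physio, soil = soil_params(),
                          lower = c(theta_wp = 0.02, theta_hc = 0.10,
                                    root_depth = 200),
                          upper = c(theta_wp = 0.25, theta_hc = 0.50,
                                    root_depth = 1500),
                          leaf = NULL, n_starts = 8, seed = 1) {
  weather <- validate_weather(weather)
  observed <- observed[order(observed$date), ]
  idx <- match(as.Date(observed$date), weather$date)
  if (all(is.na(idx))) stop("no overlap between weather and observations")
  keep <- !is.na(idx)
  obs_theta <- observed$theta[keep]
  obs_idx <- idx[keep]
  if (length(obs_idx) < 365) stop("overlap of weather and observations must cover at least 1 year")

  objective <- function(par) {
    if (par[1] >= par[2] - 1e-3) return(1e6)
    s <- soil
    s$theta_wp <- par[1]; s$theta_hc <- par[2]; s$root_depth <- par[3]
    sim <- run_water_balance(weather, s, physio, leaf = leaf)
    sqrt(mean((sim$theta[obs_idx] - obs_theta)^2))
  }

  pnames <- c("theta_wp", "theta_hc", "root_depth")
  lo <- lower[pnames]; hi <- upper[pnames]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, 3)
  starts <- sweep(sweep(design, 2, hi - lo, "*"), 2, lo, "+")

  fits <- lapply(seq_len(n_starts), function(k) {
    optim(starts[k, ], objective, method = "L-BFGS-B",
          lower = lo, upper = hi,
          control = list(parscale = c(0.1, 0.1, 500), factr = 1e10))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  par <- setNames(best$par, pnames)
  out <- soil
  out$theta_wp <- par[["theta_wp"]]; out$theta_hc <- par[["theta_hc"]]
  out$root_depth <- par[["root_depth"]]
  at_bounds <- any(abs(par - lo) < 1e-8 * pmax(1, abs(lo))) ||
    any(abs(par - hi) < 1e-8 * pmax(1, abs(hi)))
  if (at_bounds) warning("calibration hit a parameter bound")
  list(soil = out, rmse = best$value, at_bounds = at_bounds,
       starts = data.frame(starts, value = vals))
}
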