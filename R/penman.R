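# FAO-56 Penman-Monteith reference evapotranspiration (grass reference),
# computed from daily minimum/maximum temperature, mean relative humidity,
# global radiation and 2 m wind speed.

sat_vapour_pressure <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference evapotranspiration ET0 (mm/day) of the standard grass
#' surface. Net shortwave radiation uses albedo 0.23; net longwave uses the
#' Stefan-Boltzmann term with humidity and cloudiness corrections, with
#' clear-sky radiation derived from extraterrestrial radiation and site
#' elevation. Soil heat flux is taken as zero at the daily step.
#'
#' All arguments are vectorized over days.
#'
#' @param tmin,tmax daily minimum / maximum air temperature, deg C.
#' @param rh daily mean relative humidity, fraction in [0, 1].
#' @param rad daily global (shortwave) radiation, MJ m-2 day-1.
#' @param wind wind speed at 2 m, m/s.
#' @param elevation site elevation, m a.s.l.
#' @param latitude degrees north (needed for clear-sky radiation).
#' @param date \code{Date} vector (or day-of-year integers).
#' @return ET0 in mm/day, floored at 0.
#' @export
penman_monteith_et0 <- function(tmin, tmax, rh, rad, wind,
                                elevation, latitude, date) {
  if (any(rh < 0 | rh > 1, na.rm = TRUE)) {
    stop("rh must be a fraction in [0, 1]")
  }
  tmean <- (tmin + tmax) / 2
  # psychrometric constant from barometric pressure at elevation
  pres <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pres
  delta <- 4098 * sat_vapour_pressure(tmean) / (tmean + 237.3)^2
  es <- (sat_vapour_pressure(tmin) + sat_vapour_pressure(tmax)) / 2
  ea <- rh * es

  ra <- extraterrestrial_radiation(date, latitude)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * rad
  sigma <- 4.903e-9
  # relative shortwave bounded as in FAO-56: >= ~0.3 on fully overcast days
  rel <- ifelse(rso > 0, pmin(1, pmax(0.3, rad / rso)), 0.3)
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  num <- 0.408 * delta * rn +
    gamma * 900 / (tmean + 273) * wind * pmax(es - ea, 0)
  den <- delta + gamma * (1 + 0.34 * wind)
  pmax(num / den, 0)
}
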