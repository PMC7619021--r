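# Solar geometry: extraterrestrial radiation, daylength, sunshine-based
# radiation estimates and the slope/aspect correction of direct-beam
# irradiance. All formulas follow FAO-56 conventions; angles in radians
# internally, degrees at the interface.

SOLAR_CONSTANT <- 0.0820 # MJ m-2 min-1

deg2rad <- function(x) x * pi / 180

# solar declination (rad) and inverse relative earth-sun distance for a
# day-of-year
solar_declination <- function(doy) 0.409 * sin(2 * pi * doy / 365 - 1.39)
inv_rel_distance <- function(doy) 1 + 0.033 * cos(2 * pi * doy / 365)

# sunset hour angle (rad), clamped for polar day/night
sunset_hour_angle <- function(lat_rad, decl) {
  x <- -tan(lat_rad) * tan(decl)
  acos(pmin(1, pmax(-1, x)))
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere shortwave radiation on a horizontal plane, from solar
#' declination and sunset hour angle.
#'
#' @param date a \code{Date} vector (or integer day-of-year).
#' @param latitude degrees north, in (-90, 90).
#' @return MJ m-2 day-1; 0 during polar night.
#' @export
extraterrestrial_radiation <- function(date, latitude) {
  stopifnot(latitude > -90, latitude < 90)
  doy <- if (inherits(date, "Date")) doy_of(date) else as.integer(date)
  phi <- deg2rad(latitude)
  decl <- solar_declination(doy)
  ws <- sunset_hour_angle(phi, decl)
  dr <- inv_rel_distance(doy)
  ra <- (24 * 60 / pi) * SOLAR_CONSTANT * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  pmax(ra, 0)
}

#' Astronomical daylength
#'
#' @inheritParams extraterrestrial_radiation
#' @return hours in [0, 24].
#' @export
daylength <- function(date, latitude) {
  stopifnot(latitude > -90, latitude < 90)
  doy <- if (inherits(date, "Date")) doy_of(date) else as.integer(date)
  ws <- sunset_hour_angle(deg2rad(latitude), solar_declination(doy))
  24 / pi * ws
}

#' Estimate global radiation from sunshine fraction
#'
#' Angstrom-Prescott estimate \eqn{R_g = R_a (a + b \, n/N)}, where
#' \eqn{n/N} is the fraction of daytime sunshine. Defaults a = 0.25,
#' b = 0.50 are the standard values used when no local calibration exists.
#'
#' @param sunshine_frac fraction of daylight hours with bright sunshine,
#'   in [0, 1].
#' @inheritParams extraterrestrial_radiation
#' @param a,b Angstrom coefficients.
#' @return global radiation, MJ m-2 day-1; 0 during polar night.
#' @export
estimate_radiation <- function(sunshine_frac, date, latitude,
                               a = 0.25, b = 0.50) {
  if (any(sunshine_frac < 0 | sunshine_frac > 1, na.rm = TRUE)) {
    stop("sunshine_frac must be within [0, 1]")
  }
  ra <- extraterrestrial_radiation(date, latitude)
  ra * (a + b * sunshine_frac)
}

# solar elevation (sin) and azimuth (rad, clockwise from north) for a
# vector of hour angles on one day
sun_position <- function(lat_rad, decl, omega) {
  sin_alpha <- sin(lat_rad) * sin(decl) + cos(lat_rad) * cos(decl) * cos(omega)
  cos_alpha <- sqrt(pmax(0, 1 - sin_alpha^2))
  cos_psi <- ifelse(cos_alpha > 1e-12,
                    (sin(decl) - sin_alpha * sin(lat_rad)) /
                      (cos_alpha * cos(lat_rad)),
                    0)
  psi <- acos(pmin(1, pmax(-1, cos_psi)))
  psi <- ifelse(omega > 0, 2 * pi - psi, psi) # afternoon sun in the west
  list(sin_alpha = sin_alpha, cos_alpha = cos_alpha, azimuth = psi)
}

#' Slope/aspect correction factor for direct-beam radiation
#'
#' Ratio of daily direct-beam irradiance received by a tilted plane to that
#' received by a horizontal plane, found by stepping the sun across the sky
#' at a fixed interval and accumulating the cosine of the incidence angle on
#' each plane. The factor applies to the direct fraction of global
#' radiation only (see [adjust_radiation_for_terrain()]).
#'
#' @param date a single \code{Date} (or day-of-year).
#' @param latitude degrees north.
#' @param slope degrees from horizontal, in [0, 90).
#' @param aspect downslope direction, degrees clockwise from north
#'   (0 = north-facing, 180 = south-facing).
#' @param step_min integration step, minutes.
#' @return dimensionless factor; 1 on horizontal terrain or when the sun
#'   never rises.
#' @export
slope_aspect_factor <- function(date, latitude, slope, aspect,
                                step_min = 5) {
  stopifnot(slope >= 0, slope < 90, aspect >= 0, aspect < 360)
  if (slope == 0) return(1)
  doy <- if (inherits(date, "Date")) doy_of(date) else as.integer(date)
  phi <- deg2rad(latitude)
  decl <- solar_declination(doy)
  beta <- deg2rad(slope)
  gamma <- deg2rad(aspect)

  omega <- deg2rad(seq(-180, 180, by = step_min / 4)[-1]) # hour angle grid
  sp <- sun_position(phi, decl, omega)
  up <- sp$sin_alpha > 0
  if (!any(up)) return(1)

  # sun unit vector in (east, north, up); surface normal of the tilted plane
  s_e <- sp$cos_alpha * sin(sp$azimuth)
  s_n <- sp$cos_alpha * cos(sp$azimuth)
  s_u <- sp$sin_alpha
  n_e <- sin(beta) * sin(gamma)
  n_n <- sin(beta) * cos(gamma)
  n_u <- cos(beta)

  cos_tilt <- pmax(0, s_e * n_e + s_n * n_n + s_u * n_u)
  horiz <- sum(pmax(0, s_u[up]))
  if (horiz <= 0) return(1)
  sum(cos_tilt[up]) / horiz
}

#' Adjust daily global radiation for terrain
#'
#' Applies the slope/aspect factor to the direct-beam fraction of global
#' radiation, leaving the diffuse fraction untouched. When a sunshine
#' fraction is supplied, the direct fraction is derived from the Angstrom
#' partition \eqn{b n/N / (a + b n/N)}; otherwise a fixed direct fraction
#' is used.
#'
#' @param rad global radiation on the horizontal, MJ m-2 day-1.
#' @param date \code{Date} vector matching \code{rad}.
#' @param latitude,slope,aspect site physiography (degrees).
#' @param sunshine_frac optional sunshine fraction vector.
#' @param direct_frac fallback direct-beam fraction when no sunshine data.
#' @param a,b Angstrom coefficients used for the partition.
#' @return adjusted radiation vector, MJ m-2 day-1.
#' @export
adjust_radiation_for_terrain <- function(rad, date, latitude, slope, aspect,
                                         sunshine_frac = NULL,
                                         direct_frac = 0.5,
                                         a = 0.25, b = 0.50) {
  if (slope == 0) return(rad)
  fdir <- if (!is.null(sunshine_frac)) {
    (b * sunshine_frac) / (a + b * sunshine_frac)
  } else {
    rep(direct_frac, length(rad))
  }
  doy <- doy_of(date)
  udoy <- unique(doy)
  fac <- vapply(udoy, function(d) {
    slope_aspect_factor(d, latitude, slope, aspect)
  }, numeric(1))
  f <- fac[match(doy, udoy)]
  rad * (fdir * f + (1 - fdir))
}
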