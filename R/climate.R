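# Climate engine: weather validation, the looped-baseline future series and
# seasonal delta-change scenarios.

#' Validate a daily weather table
#'
#' Canonical columns: \code{date} (Date), \code{tmin}, \code{tmax},
#' \code{tmean} (deg C), \code{precip} (mm), \code{rh} (fraction),
#' \code{wind} (m/s), and at least one of \code{rad} (MJ m-2 day-1) or
#' \code{sunshine_frac}. \code{tmean} is filled as (tmin+tmax)/2 when
#' absent.
#'
#' @param weather data frame.
#' @return the validated (possibly completed) data frame, sorted by date.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "precip", "rh", "wind")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!inherits(weather$date, "Date")) weather$date <- as.Date(weather$date)
  if (is.null(weather$tmean)) weather$tmean <- (weather$tmin + weather$tmax) / 2
  if (is.null(weather$rad) && is.null(weather$sunshine_frac)) {
    stop("weather needs `rad` or `sunshine_frac`")
  }
  weather <- weather[order(weather$date), , drop = FALSE]
  with(weather, {
    if (any(tmin > tmax + 1e-9)) stop("tmin > tmax found")
    if (any(precip < 0)) stop("negative precipitation found")
    if (any(rh < 0 | rh > 1)) stop("rh must be a fraction in [0, 1]")
  })
  rownames(weather) <- NULL
  weather
}

#' Fill gaps in one weather variable by linear transfer from a reference
#'
#' Missing values of \code{var} are predicted from a reference series by
#' ordinary least squares over the overlapping (complete) days — the
#' minimal transfer used to extend station records backwards or patch
#' gridded gaps.
#'
#' @param weather weather table with a gap-ridden column \code{var}.
#' @param reference data frame with columns \code{date} and \code{var}.
#' @param var column name to fill.
#' @return weather with gaps filled; attribute \code{"n_filled"} records
#'   the count.
#' @export
fill_gaps_by_regression <- function(weather, reference, var) {
  stopifnot(var %in% names(weather), var %in% names(reference))
  ref <- reference[match(weather$date, reference$date), var]
  y <- weather[[var]]
  ok <- is.finite(y) & is.finite(ref)
  gap <- !is.finite(y) & is.finite(ref)
  if (!any(gap)) return(weather)
  if (sum(ok) < 10) stop("fewer than 10 overlapping days for gap filling")
  fit <- lm(y[ok] ~ ref[ok])
  weather[[var]][gap] <- coef(fit)[1] + coef(fit)[2] * ref[gap]
  attr(weather, "n_filled") <- sum(gap)
  weather
}

#' Build a looped-baseline future weather series
#'
#' Fills a projection window by cycling a fixed historical source window in
#' order, restarting at its beginning when exhausted; the records keep their
#' weather values but are relabelled to the projection calendar. This is
#' the constant-climate counterfactual against which delta-change scenarios
#' are compared.
#'
#' @param history daily weather table covering the source window.
#' @param loop_window length-2 Date (or coercible) vector: first and last
#'   day of the source window.
#' @param projection_window length-2 Date vector: first and last day to
#'   generate (empty output if end < start).
#' @return weather table for the projection window, with a
#'   \code{source_date} column recording provenance.
#' @export
build_baseline_loop <- function(history, loop_window, projection_window) {
  loop_window <- as.Date(loop_window)
  projection_window <- as.Date(projection_window)
  history <- validate_weather(history)
  src_days <- seq(loop_window[1], loop_window[2], by = "day")
  idx <- match(src_days, history$date)
  if (anyNA(idx)) {
    stop("source window has missing days: ",
         paste(format(head(src_days[is.na(idx)], 10)), collapse = ", "))
  }
  src <- history[idx, , drop = FALSE]
  proj_days <- if (projection_window[2] < projection_window[1]) {
    as.Date(character())
  } else {
    seq(projection_window[1], projection_window[2], by = "day")
  }
  n <- length(proj_days)
  if (n == 0L) {
    out <- src[0, , drop = FALSE]
    out$source_date <- as.Date(character())
    return(out)
  }
  take <- ((seq_len(n) - 1L) %% length(src_days)) + 1L
  out <- src[take, , drop = FALSE]
  out$source_date <- out$date
  out$date <- proj_days
  rownames(out) <- NULL
  out
}

#' Seasonal delta-change scenario specification
#'
#' A scenario is a set of end-of-century seasonal temperature offsets
#' (deg C, added to tmin and tmax) and precipitation multipliers
#' (dimensionless), ramped linearly from no change at \code{ramp_start} to
#' the endpoint at \code{ramp_end}. The season system is the package's
#' five-block calendar.
#'
#' The packaged endpoint tables follow regional downscaled scenarios for
#' north-eastern Austria: under the high-emission pathway, roughly +4 deg C
#' in winter and +3 deg C in summer by 2100, with winter precipitation up
#' about 20% and summer about 5%; the moderate pathway is about half as
#' strong.
#'
#' @param name one of \code{"baseline"}, \code{"rcp45"}, \code{"rcp85"}, or
#'   \code{"custom"}.
#' @param temp_offset_end named numeric: end-of-ramp offset per season.
#' @param precip_mult_end named numeric: end-of-ramp multiplier per season.
#' @param ramp_start,ramp_end calendar years bounding the linear ramp.
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name = c("baseline", "rcp45", "rcp85", "custom"),
                          temp_offset_end = NULL, precip_mult_end = NULL,
                          ramp_start = 2025, ramp_end = 2100) {
  name <- match.arg(name)
  defaults <- list(
    baseline = list(off = c(JanMar = 0, AprMay = 0, JunJul = 0,
                            AugSep = 0, OctDec = 0),
                    mul = c(JanMar = 1, AprMay = 1, JunJul = 1,
                            AugSep = 1, OctDec = 1)),
    rcp45 = list(off = c(JanMar = 2.0, AprMay = 1.75, JunJul = 1.5,
                         AugSep = 1.5, OctDec = 2.0),
                 mul = c(JanMar = 1.10, AprMay = 1.05, JunJul = 1.025,
                         AugSep = 1.025, OctDec = 1.10)),
    rcp85 = list(off = c(JanMar = 4.0, AprMay = 3.5, JunJul = 3.0,
                         AugSep = 3.0, OctDec = 4.0),
                 mul = c(JanMar = 1.20, AprMay = 1.10, JunJul = 1.05,
                         AugSep = 1.05, OctDec = 1.20))
  )
  if (name != "custom") {
    temp_offset_end <- temp_offset_end %||% defaults[[name]]$off
    precip_mult_end <- precip_mult_end %||% defaults[[name]]$mul
  }
  if (is.null(temp_offset_end) || is.null(precip_mult_end)) {
    stop("custom scenarios need temp_offset_end and precip_mult_end")
  }
  stopifnot(setequal(names(temp_offset_end), season_levels()),
            setequal(names(precip_mult_end), season_levels()))
  if (any(precip_mult_end < 0)) stop("precipitation multipliers must be >= 0")
  if (any(!is.finite(temp_offset_end))) stop("offsets must be finite")
  structure(list(name = name,
                 temp_offset_end = temp_offset_end[season_levels()],
                 precip_mult_end = precip_mult_end[season_levels()],
                 ramp_start = ramp_start, ramp_end = ramp_end),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "\n")
  cat("  ramp:", x$ramp_start, "->", x$ramp_end, "\n")
  cat("  temp offset end (degC):\n")
  print(round(x$temp_offset_end, 2))
  cat("  precip multiplier end:\n")
  print(round(x$precip_mult_end, 3))
  invisible(x)
}

# ramp weight in [0, 1] for a calendar year
scenario_ramp <- function(spec, year) {
  pmin(1, pmax(0, (year - spec$ramp_start) /
                  (spec$ramp_end - spec$ramp_start)))
}

#' Temperature offset / precipitation multiplier at a (season, year)
#'
#' @param spec a [scenario_spec()].
#' @param season season code(s).
#' @param year calendar year(s).
#' @return numeric vector.
#' @export
scenario_temp_offset <- function(spec, season, year) {
  unname(spec$temp_offset_end[season]) * scenario_ramp(spec, year)
}

#' @rdname scenario_temp_offset
#' @export
scenario_precip_multiplier <- function(spec, season, year) {
  1 + (unname(spec$precip_mult_end[season]) - 1) * scenario_ramp(spec, year)
}

#' Apply a delta-change scenario to a daily weather series
#'
#' Adds the seasonal temperature offset to tmin and tmax (tmean is
#' recomputed as their midpoint) and multiplies precipitation by the
#' seasonal factor. Humidity, wind and radiation are left unchanged.
#'
#' @param series daily weather table.
#' @param spec a [scenario_spec()].
#' @return modified weather table.
#' @export
apply_scenario <- function(series, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  series <- validate_weather(series)
  season <- season_of_month(series$date)
  year <- year_of(series$date)
  off <- scenario_temp_offset(spec, season, year)
  mul <- scenario_precip_multiplier(spec, season, year)
  if (any(mul < 0)) stop("negative precipitation multiplier")
  series$tmin <- series$tmin + off
  series$tmax <- series$tmax + off
  series$tmean <- (series$tmin + series$tmax) / 2
  series$precip <- series$precip * mul
  series
}
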