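# Plain-text interchange: the weather and ring CSV dialects, growth-factor
# long CSV with a YAML moments sidecar, and YAML (de)serialization of
# parameter objects.

#' Read / write the daily weather CSV dialect
#'
#' Columns: date (ISO-8601), tmin_c, tmax_c, precip_mm, rh_frac, wind_ms,
#' and rad_mj_m2 and/or sunshine_frac.
#'
#' @param path file path.
#' @param weather canonical weather table (see [validate_weather()]).
#' @return \code{read_weather_csv} returns a validated weather table.
#' @export
read_weather_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  map <- c(tmin_c = "tmin", tmax_c = "tmax", tmean_c = "tmean",
           precip_mm = "precip", rh_frac = "rh", wind_ms = "wind",
           rad_mj_m2 = "rad")
  for (nm in names(map)) {
    if (nm %in% names(d)) names(d)[names(d) == nm] <- map[[nm]]
  }
  d$date <- as.Date(d$date)
  validate_weather(d)
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  weather <- validate_weather(weather)
  out <- data.frame(date = format(weather$date, "%Y-%m-%d"),
                    tmin_c = weather$tmin, tmax_c = weather$tmax,
                    precip_mm = weather$precip, rh_frac = weather$rh,
                    wind_ms = weather$wind)
  if (!is.null(weather$rad)) out$rad_mj_m2 <- weather$rad
  if (!is.null(weather$sunshine_frac)) {
    out$sunshine_frac <- weather$sunshine_frac
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write ring-width series CSV
#'
#' Columns: species, site_id, tree_id, year, age, width_mm (mapped to the
#' internal \code{w_obs}).
#'
#' @param path file path.
#' @param rings ring table with \code{w_obs} in mm.
#' @export
read_rings_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("width_mm" %in% names(d)) names(d)[names(d) == "width_mm"] <- "w_obs"
  stopifnot(all(c("site_id", "tree_id", "year", "age", "w_obs")
                %in% names(d)))
  d
}

#' @rdname read_rings_csv
#' @export
write_rings_csv <- function(rings, path) {
  out <- rings
  if ("w_obs" %in% names(out)) names(out)[names(out) == "w_obs"] <- "width_mm"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read standardized growth factors with a moments sidecar
#'
#' The long CSV carries site_id, growth_year, season, lag, factor,
#' raw_value, std_value; the YAML sidecar stores the standardization
#' moments so scenario records can reuse the frozen historical baseline.
#'
#' @param std a [standardize_factors()] result.
#' @param csv_path,moments_path file paths.
#' @export
write_factors_csv <- function(std, csv_path, moments_path = NULL) {
  write.csv(std$records, csv_path, row.names = FALSE)
  if (!is.null(moments_path)) {
    m <- std$moments
    yaml::write_yaml(
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])),
      moments_path, precision = 15)
  }
  invisible(csv_path)
}

#' @rdname write_factors_csv
#' @export
read_factors_csv <- function(csv_path, moments_path = NULL) {
  records <- read.csv(csv_path, stringsAsFactors = FALSE)
  moments <- NULL
  if (!is.null(moments_path)) {
    m <- yaml::read_yaml(moments_path)
    moments <- do.call(rbind, lapply(m, as.data.frame))
  }
  list(records = records, moments = moments)
}

#' Serialize parameter objects to YAML
#'
#' Works for [soil_params()], [age_curve_params()], [pheno_params()] and
#' [scenario_spec()] objects.
#'
#' @param x parameter object.
#' @param path file path.
#' @param class_name class to restore on read.
#' @export
write_params_yaml <- function(x, path) {
  yaml::write_yaml(c(list(.class = class(x)[1]),
                     lapply(unclass(x), function(v) {
                       if (is.numeric(v) && !is.null(names(v))) as.list(v)
                       else v
                     })), path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path, class_name = NULL) {
  raw <- yaml::read_yaml(path)
  cls <- class_name %||% raw$.class
  raw$.class <- NULL
  raw <- lapply(raw, function(v) {
    if (is.list(v) && all(vapply(v, is.numeric, logical(1)))) unlist(v)
    else v
  })
  structure(raw, class = cls)
}
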