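# Seasonal growth factors: aggregate daily weather and water-balance
# output into seven seasonal summaries per site and year, attach the
# one- and two-year lag structure, and standardize per
# (factor, season, lag) stratum.

#' Aggregate one season window into the seven growth factors
#'
#' @param daily data frame with one row per day: \code{date},
#'   \code{tmean}, \code{precip}, \code{t_act}, \code{t_pot},
#'   \code{theta}, \code{rew}.
#' @param year calendar year of the window.
#' @param season season code (see [season_levels()]).
#' @param strict logical: stress-day counting uses strict \code{<}.
#' @return named numeric vector of the seven raw factor values:
#'   mean_temp (deg C), transp_sum (mm), climatic_wb (mm, precipitation
#'   minus actual transpiration), transp_deficit (mm),
#'   mean_soil_moisture (volumetric), days_rew_lt_04, days_rew_lt_07.
#' @export
aggregate_season <- function(daily, year, season, strict = TRUE) {
  months <- season_months(season)
  first <- as.Date(sprintf("%d-%02d-01", year, months[1]))
  last_m <- months[length(months)]
  last <- seq(as.Date(sprintf("%d-%02d-01", year, last_m)),
              by = "month", length.out = 2)[2] - 1
  want <- seq(first, last, by = "day")
  idx <- match(want, daily$date)
  if (anyNA(idx)) {
    stop("window ", year, "/", season, " has missing dates: ",
         paste(format(head(want[is.na(idx)], 5)), collapse = ", "))
  }
  d <- daily[idx, , drop = FALSE]
  c(mean_temp = mean(d$tmean),
    transp_sum = sum(d$t_act),
    climatic_wb = sum(d$precip) - sum(d$t_act),
    transp_deficit = sum(d$t_pot - d$t_act),
    mean_soil_moisture = mean(d$theta),
    days_rew_lt_04 = count_stress_days(d$rew, 0.4, strict),
    days_rew_lt_07 = count_stress_days(d$rew, 0.7, strict))
}

#' Build raw seasonal growth factors for one site
#'
#' Runs [aggregate_season()] over every (year, season) block fully covered
#' by the daily record.
#'
#' @param daily merged daily table: weather (\code{date}, \code{tmean},
#'   \code{precip}) plus water-balance output (\code{t_act}, \code{t_pot},
#'   \code{theta}, \code{rew}).
#' @param site_id site identifier stored on the output.
#' @param years calendar years to aggregate (default: all complete ones).
#' @param strict passed to [aggregate_season()].
#' @return long data frame: site_id, year, season, factor, raw_value.
#' @export
build_growth_factors <- function(daily, site_id, years = NULL,
                                 strict = TRUE) {
  stopifnot(all(c("date", "tmean", "precip", "t_act", "t_pot",
                  "theta", "rew") %in% names(daily)))
  daily <- daily[order(daily$date), , drop = FALSE]
  yr <- year_of(daily$date)
  if (is.null(years)) {
    cnt <- table(yr)
    years <- as.integer(names(cnt)[cnt >= 365])
  }
  keep <- yr %in% years
  d <- daily[keep, , drop = FALSE]
  yr <- yr[keep]
  season <- season_of_month(d$date)
  g <- factor(paste(yr, season, sep = "|"),
              levels = as.vector(outer(years, season_levels(),
                                       paste, sep = "|")))
  # every (year, season) block must be gap-free
  expect_n <- vapply(levels(g), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    months <- season_months(p[2])
    y <- as.integer(p[1])
    first <- as.Date(sprintf("%d-%02d-01", y, months[1]))
    nxt <- seq(as.Date(sprintf("%d-%02d-01", y, months[length(months)])),
               by = "month", length.out = 2)[2]
    as.integer(nxt - first)
  }, integer(1))
  got_n <- as.integer(table(g))
  if (any(got_n != expect_n)) {
    bad <- levels(g)[got_n != expect_n]
    stop("season window(s) with missing dates: ",
         paste(head(bad, 5), collapse = ", "))
  }
  lt <- if (strict) `<` else `<=`
  vals <- cbind(
    mean_temp = as.numeric(tapply(d$tmean, g, mean)),
    transp_sum = as.numeric(rowsum(d$t_act, g)),
    climatic_wb = as.numeric(rowsum(d$precip - d$t_act, g)),
    transp_deficit = as.numeric(rowsum(d$t_pot - d$t_act, g)),
    mean_soil_moisture = as.numeric(tapply(d$theta, g, mean)),
    days_rew_lt_04 = as.numeric(rowsum(as.numeric(lt(d$rew, 0.4)), g)),
    days_rew_lt_07 = as.numeric(rowsum(as.numeric(lt(d$rew, 0.7)), g)))
  parts <- do.call(rbind, strsplit(levels(g), "|", fixed = TRUE))
  out <- data.frame(
    site_id = site_id,
    year = rep(as.integer(parts[, 1]), times = ncol(vals)),
    season = rep(parts[, 2], times = ncol(vals)),
    factor = rep(colnames(vals), each = nrow(vals)),
    raw_value = as.vector(vals))
  out <- out[order(out$year, match(out$season, season_levels()),
                   match(out$factor, growth_factor_levels())), ]
  rownames(out) <- NULL
  out
}

#' Attach the lag structure to raw seasonal factors
#'
#' For every growth year with at least two preceding years of factors,
#' emits the current-year (\code{act}) records for the four seasons up to
#' September, and copies of the previous (\code{m1}) and
#' second-previous (\code{m2}) calendar year's values for all five
#' seasons. Growth years without sufficient history are dropped.
#'
#' @param raw output of [build_growth_factors()] (may span several sites).
#' @return long data frame: site_id, growth_year, season, lag, factor,
#'   raw_value.
#' @export
attach_lags <- function(raw) {
  stopifnot(all(c("site_id", "year", "season", "factor", "raw_value")
                %in% names(raw)))
  out <- lapply(split(raw, raw$site_id), function(d) {
    yrs <- sort(unique(d$year))
    res <- lapply(yrs, function(gy) {
      if (!((gy - 1) %in% yrs && (gy - 2) %in% yrs)) return(NULL)
      act <- d[d$year == gy & d$season != "OctDec", , drop = FALSE]
      m1 <- d[d$year == gy - 1, , drop = FALSE]
      m2 <- d[d$year == gy - 2, , drop = FALSE]
      act$lag <- "act"; m1$lag <- "m1"; m2$lag <- "m2"
      o <- rbind(act, m1, m2)
      o$growth_year <- gy
      o
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    stop("no growth year has two preceding years of factors")
  }
  dropped <- length(unique(raw$year)) - length(unique(out$growth_year))
  if (dropped > 0) {
    message(dropped, " growth year(s) dropped for insufficient lag history")
  }
  out <- out[, c("site_id", "growth_year", "season", "lag", "factor",
                 "raw_value")]
  rownames(out) <- NULL
  out
}

#' Standardize growth factors per (factor, season, lag) stratum
#'
#' Z-scores are computed with the mean and standard deviation of each
#' stratum over a historical reference window, pooling sites and years.
#' The moments are returned (and accepted back) so scenario records can be
#' standardized against the frozen historical baseline: appending future
#' years never changes historical z-scores.
#'
#' @param records lagged factor records (see [attach_lags()]).
#' @param reference length-2 integer vector of growth years bounding the
#'   standardization window (ignored when \code{moments} is supplied).
#' @param moments optional frozen moments data frame from an earlier call.
#' @return list with \code{records} (input plus \code{std_value}) and
#'   \code{moments} (factor, season, lag, mean, sd, constant).
#' @export
standardize_factors <- function(records, reference = NULL, moments = NULL) {
  key <- paste(records$factor, records$season, records$lag, sep = "|")
  if (is.null(moments)) {
    if (is.null(reference)) {
      reference <- range(records$growth_year)
    }
    if (diff(reference) + 1 < 5) stop("reference window needs >= 5 years")
    ref <- records[records$growth_year >= reference[1] &
                     records$growth_year <= reference[2], , drop = FALSE]
    if (!nrow(ref)) stop("reference window contains no records")
    rkey <- paste(ref$factor, ref$season, ref$lag, sep = "|")
    mu <- tapply(ref$raw_value, rkey, mean)
    sg <- tapply(ref$raw_value, rkey, sd)
    moments <- data.frame(
      key = names(mu),
      mean = as.numeric(mu),
      sd = as.numeric(sg),
      constant = !is.finite(as.numeric(sg)) | as.numeric(sg) < 1e-12
    )
    parts <- do.call(rbind, strsplit(moments$key, "|", fixed = TRUE))
    moments$factor <- parts[, 1]; moments$season <- parts[, 2]
    moments$lag <- parts[, 3]
    if (any(moments$constant)) {
      warning("constant factor stratum(s) flagged: ",
              paste(moments$key[moments$constant], collapse = ", "))
    }
  }
  i <- match(key, moments$key)
  if (anyNA(i)) stop("records contain strata without stored moments: ",
                     paste(unique(key[is.na(i)]), collapse = ", "))
  std <- (records$raw_value - moments$mean[i]) / moments$sd[i]
  std[moments$constant[i]] <- 0
  records$std_value <- std
  list(records = records,
       moments = moments[, c("key", "factor", "season", "lag",
                             "mean", "sd", "constant")])
}

#' Pivot standardized factors to a wide model frame
#'
#' One row per (site_id, growth_year); one column per
#' (factor, season, lag) term named \code{factor_season_lag}.
#'
#' @param records standardized factor records (with \code{std_value}).
#' @param terms optional data frame (factor, season, lag) restricting the
#'   columns.
#' @return wide data frame.
#' @export
factors_wide <- function(records, terms = NULL) {
  if (!is.null(terms)) {
    want <- term_name(terms$factor, terms$season, terms$lag)
    key <- term_name(records$factor, records$season, records$lag)
    records <- records[key %in% want, , drop = FALSE]
  }
  term <- term_name(records$factor, records$season, records$lag)
  uterm <- unique(term)
  rowkey <- paste(records$site_id, records$growth_year, sep = "\r")
  urow <- unique(rowkey)
  m <- matrix(NA_real_, nrow = length(urow), ncol = length(uterm),
              dimnames = list(NULL, uterm))
  m[cbind(match(rowkey, urow), match(term, uterm))] <- records$std_value
  parts <- do.call(rbind, strsplit(urow, "\r", fixed = TRUE))
  wide <- data.frame(site_id = parts[, 1],
                     growth_year = as.integer(parts[, 2]))
  wide <- cbind(wide, as.data.frame(m))
  wide[order(wide$site_id, wide$growth_year), , drop = FALSE]
}
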