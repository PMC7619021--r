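# Shared helpers: the five-season calendar, factor vocabulary, small checks.

#' Season and lag vocabulary
#'
#' The year is partitioned into five blocks: January--March, April--May,
#' June--July, August--September and October--December. The growing season
#' (April--September) is split into three two-month blocks; the dormant
#' season into two three-month blocks. Lags are coded \code{"act"} (the
#' growth year itself), \code{"m1"} (previous year) and \code{"m2"} (two
#' years before). Ring formation is assumed complete by the end of
#' September, so \code{("OctDec", "act")} is not a legal combination.
#'
#' @return \code{season_levels()} and \code{lag_levels()} return character
#'   vectors; \code{legal_season_keys()} a data frame with columns
#'   \code{season} and \code{lag} (14 rows); \code{growth_factor_levels()}
#'   the canonical names of the seven growth factors.
#' @export
season_levels <- function() {
  c("JanMar", "AprMay", "JunJul", "AugSep", "OctDec")
}

#' @rdname season_levels
#' @export
lag_levels <- function() c("act", "m1", "m2")

#' @rdname season_levels
#' @export
legal_season_keys <- function() {
  keys <- expand.grid(season = season_levels(), lag = lag_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys[!(keys$season == "OctDec" & keys$lag == "act"), , drop = FALSE]
}

#' @rdname season_levels
#' @export
growth_factor_levels <- function() {
  c("mean_temp", "transp_sum", "climatic_wb", "transp_deficit",
    "mean_soil_moisture", "days_rew_lt_04", "days_rew_lt_07")
}

# water-category factors, in the canonical order used for tie-breaking
water_factor_levels <- function() setdiff(growth_factor_levels(), "mean_temp")

#' Season of a calendar month or date
#'
#' @param month integer month 1--12, or a \code{Date} vector.
#' @return character season codes (see [season_levels()]).
#' @export
season_of_month <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  stopifnot(all(month %in% 1:12))
  cut(month, breaks = c(0, 3, 5, 7, 9, 12), labels = season_levels()) |>
    as.character()
}

# month span of one season block
season_months <- function(season) {
  switch(season,
    JanMar = 1:3, AprMay = 4:5, JunJul = 6:7, AugSep = 8:9, OctDec = 10:12,
    stop("unknown season: ", season))
}

# model-frame column name for one (factor, season, lag) term
term_name <- function(factor, season, lag) paste(factor, season, lag, sep = "_")

doy_of <- function(date) as.integer(format(date, "%j"))
year_of <- function(date) as.integer(format(date, "%Y"))
month_of <- function(date) as.integer(format(date, "%m"))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
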