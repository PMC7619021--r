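# Projection: drive a fitted sensitivity model with scenario growth
# factors (standardized against the frozen historical moments) to produce
# annual ring-width-residual trajectories and 20-year period summaries.

#' Project ring-width residuals under a scenario
#'
#' Population-level prediction: for every (site, year) the predicted
#' residual is the intercept plus the sum of retained estimates times the
#' scenario's standardized factors; random site intercepts are set to
#' zero. Predictions are averaged over sites per year.
#'
#' @param model a \code{sensitivity_model}.
#' @param scenario_factors standardized factor records for the scenario,
#'   produced with the historical standardization moments.
#' @param scenario name stored on the output.
#' @return data frame: species, scenario, year, predicted_residual (mm);
#'   attribute \code{"by_site"} holds the per-site predictions.
#' @export
project_growth <- function(model, scenario_factors, scenario = "scenario") {
  stopifnot(inherits(model, "sensitivity_model"))
  terms <- model$terms
  if (length(terms) == 0) {
    yrs <- sort(unique(scenario_factors$growth_year))
    out <- data.frame(species = model$species %||% NA_character_,
                      scenario = scenario, year = yrs,
                      predicted_residual = model$intercept)
    return(out)
  }
  wide <- factors_wide(scenario_factors)
  miss <- setdiff(terms, names(wide))
  if (length(miss)) {
    stop("scenario factors do not cover retained term(s): ",
         paste(miss, collapse = ", "))
  }
  ok <- complete.cases(wide[, terms, drop = FALSE])
  wide <- wide[ok, , drop = FALSE]
  X <- as.matrix(wide[, terms, drop = FALSE])
  wide$pred <- model$intercept + drop(X %*% model$estimates$estimate)
  ann <- aggregate(pred ~ growth_year, data = wide, FUN = mean)
  out <- data.frame(species = model$species %||% NA_character_,
                    scenario = scenario, year = ann$growth_year,
                    predicted_residual = ann$pred)
  attr(out, "by_site") <- wide[, c("site_id", "growth_year", "pred")]
  out
}

#' Summarize an annual series over consecutive period blocks
#'
#' Means over consecutive blocks (default 20 years) anchored on a fixed
#' year so that 2081--2100 forms a block; incomplete blocks are flagged
#' and excluded by default. When a baseline series is supplied, per-period
#' deltas (scenario minus baseline) are added.
#'
#' @param annual data frame with \code{year} and a value column
#'   (\code{predicted_residual} or the first non-year numeric column).
#' @param block_years period length in years.
#' @param anchor first year of the period grid.
#' @param baseline optional annual data frame of the same shape.
#' @param keep_partial keep incomplete blocks (flagged) instead of
#'   dropping them.
#' @return data frame: period_start, period_end, n_years, mean (and
#'   \code{delta_vs_baseline} when a baseline is given), complete.
#' @export
period_summary <- function(annual, block_years = 20, anchor = 2001,
                           baseline = NULL, keep_partial = FALSE) {
  value_col <- setdiff(names(annual)[vapply(annual, is.numeric,
                                            logical(1))], "year")[1]
  ps <- anchor + floor((annual$year - anchor) / block_years) * block_years
  m <- tapply(annual[[value_col]], ps, mean)
  cnt <- tapply(annual$year, ps, length)
  agg <- data.frame(period_start = as.integer(names(m)),
                    mean = as.numeric(m),
                    n_years = as.integer(cnt))
  agg$period_end <- agg$period_start + block_years - 1
  agg$complete <- agg$n_years == block_years
  if (!keep_partial) agg <- agg[agg$complete, , drop = FALSE]
  out <- agg[, c("period_start", "period_end", "n_years", "mean",
                 "complete")]
  if (!is.null(baseline)) {
    base <- period_summary(baseline, block_years = block_years,
                           anchor = anchor, keep_partial = keep_partial)
    i <- match(out$period_start, base$period_start)
    if (anyNA(i)) stop("baseline does not cover all scenario periods")
    out$delta_vs_baseline <- out$mean - base$mean[i]
  }
  rownames(out) <- NULL
  out
}
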