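# Growing-season phenology of a deciduous (beech-type) stand: leaf
# unfolding (LU, BBCH-11) from accumulated photoperiod-weighted thermal
# forcing, and leaf coloring (LC, BBCH-94) from late-spring and
# late-summer mean temperatures.

#' Phenology model parameters
#'
#' Leaf unfolding: daily forcing \eqn{max(T - T_{base}, 0)} is weighted by
#' a photoperiodic term \eqn{(daylength/24)^{e}} and accumulated from
#' \code{forcing_start_doy}; LU is the first day the sum reaches
#' \code{F_crit}. Leaf coloring is linear in the mean temperatures of a
#' late-spring and a late-summer window: cool springs and warm late
#' summers delay senescence, so both coefficients are non-negative and
#' enter with opposite signs.
#'
#' Defaults give mid-latitude beech behaviour: LU in late April and LC in
#' mid October at the packaged synthetic climate.
#'
#' @param t_base forcing threshold temperature, deg C.
#' @param photo_exponent exponent of the normalized-daylength photoperiod
#'   weight (0 disables it).
#' @param f_crit critical forcing sum (deg C day units).
#' @param forcing_start_doy day-of-year accumulation starts.
#' @param lc_intercept baseline leaf-coloring day-of-year.
#' @param lc_coef_spring delay per deg C of spring cooling (>= 0),
#'   days/deg C.
#' @param lc_coef_summer delay per deg C of late-summer warming (>= 0),
#'   days/deg C.
#' @param spring_window,summer_window day-of-year ranges (length 2) of the
#'   two temperature windows.
#' @return an object of class \code{pheno_params}.
#' @export
pheno_params <- function(t_base = 4, photo_exponent = 1, f_crit = 110,
                         forcing_start_doy = 1,
                         lc_intercept = 283, lc_coef_spring = 1.5,
                         lc_coef_summer = 2,
                         spring_window = c(121, 181),
                         summer_window = c(213, 273)) {
  stopifnot(f_crit > 0, photo_exponent >= 0,
            lc_coef_spring >= 0, lc_coef_summer >= 0,
            length(spring_window) == 2, length(summer_window) == 2,
            spring_window[1] <= spring_window[2],
            summer_window[1] <= summer_window[2],
            spring_window[2] < summer_window[1])
  structure(list(t_base = t_base, photo_exponent = photo_exponent,
                 f_crit = f_crit, forcing_start_doy = forcing_start_doy,
                 lc_intercept = lc_intercept,
                 lc_coef_spring = lc_coef_spring,
                 lc_coef_summer = lc_coef_summer,
                 spring_window = spring_window,
                 summer_window = summer_window),
            class = "pheno_params")
}

#' @export
print.pheno_params <- function(x, ...) {
  cat("<pheno_params>\n")
  cat(sprintf("  LU: t_base = %.1f degC, photoperiod exponent = %.2f, F_crit = %.1f (start doy %d)\n",
              x$t_base, x$photo_exponent, x$f_crit, x$forcing_start_doy))
  cat(sprintf("  LC: %.1f - %.2f * T_spring + %.2f * T_summer (doy windows %d-%d, %d-%d)\n",
              x$lc_intercept, x$lc_coef_spring, x$lc_coef_summer,
              x$spring_window[1], x$spring_window[2],
              x$summer_window[1], x$summer_window[2]))
  invisible(x)
}

# photoperiod-weighted daily forcing for one year of tmean
forcing_series <- function(tmean, doy, latitude, params) {
  dl <- daylength(doy, latitude)
  pmax(tmean - params$t_base, 0) * (dl / 24)^params$photo_exponent
}

#' Predict leaf unfolding day
#'
#' @param weather one calendar year of daily weather (needs \code{date},
#'   \code{tmean}).
#' @param latitude degrees north.
#' @param params a [pheno_params()].
#' @return day-of-year of leaf unfolding, or \code{NA} when the forcing
#'   sum never reaches the threshold.
#' @export
predict_leaf_unfolding <- function(weather, latitude, params = pheno_params()) {
  doy <- doy_of(weather$date)
  o <- order(doy)
  doy <- doy[o]
  tmean <- weather$tmean[o]
  use <- doy >= params$forcing_start_doy
  f <- forcing_series(tmean[use], doy[use], latitude, params)
  cum <- cumsum(f)
  hit <- which(cum >= params$f_crit)
  if (!length(hit)) return(NA_integer_)
  doy[use][hit[1]]
}

#' Predict leaf coloring day
#'
#' @inheritParams predict_leaf_unfolding
#' @param lu optional leaf-unfolding day used as a lower clamp.
#' @return day-of-year of leaf coloring, rounded and clamped to
#'   [lu + 1, 365].
#' @export
predict_leaf_coloring <- function(weather, params = pheno_params(),
                                  lu = NULL) {
  doy <- doy_of(weather$date)
  t_spring <- mean(weather$tmean[doy >= params$spring_window[1] &
                                   doy <= params$spring_window[2]])
  t_summer <- mean(weather$tmean[doy >= params$summer_window[1] &
                                   doy <= params$summer_window[2]])
  lc <- params$lc_intercept - params$lc_coef_spring * t_spring +
    params$lc_coef_summer * t_summer
  lc <- round(lc)
  lo <- if (!is.null(lu) && is.finite(lu)) lu + 1 else 1
  as.integer(min(365, max(lo, lc)))
}

#' Predict the growing season for every year of a weather series
#'
#' @param weather multi-year daily weather.
#' @param latitude degrees north.
#' @param params a [pheno_params()].
#' @return data frame: year, lu, lc (days-of-year). Years where LU is not
#'   reached carry NA for lu and the unclamped LC.
#' @export
predict_growing_season <- function(weather, latitude,
                                   params = pheno_params()) {
  yr <- year_of(weather$date)
  out <- lapply(split(weather, yr), function(wy) {
    lu <- predict_leaf_unfolding(wy, latitude, params)
    lc <- predict_leaf_coloring(wy, params, lu = lu)
    data.frame(year = year_of(wy$date[1]), lu = lu, lc = lc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$year), , drop = FALSE]
}

#' Fit the phenology models to observed event days
#'
#' Leaf unfolding is fitted by grid search over the forcing threshold and
#' photoperiod exponent with an inner one-dimensional search for the
#' critical forcing sum; leaf coloring by ordinary least squares on the
#' two window mean temperatures (coefficients clipped at zero to preserve
#' the sign convention). The two models are fitted independently, each
#' minimizing the RMSE of predicted vs observed event days.
#'
#' @param observations data frame with columns \code{year}, \code{lu_doy},
#'   \code{lc_doy} (either may be NA in a given year).
#' @param weather multi-year daily weather covering the observation years.
#' @param latitude degrees north.
#' @param t_base_grid,exponent_grid grids searched for the LU model.
#' @param template [pheno_params()] supplying fixed settings (windows,
#'   accumulation start).
#' @return list with \code{params} (fitted [pheno_params()]),
#'   \code{rmse_lu}, \code{rmse_lc}.
#' @export
fit_phenology <- function(observations, weather, latitude,
                          t_base_grid = seq(0, 8, by = 1),
                          exponent_grid = c(0, 0.5, 1, 2),
                          template = pheno_params()) {
  if (nrow(observations) == 0) stop("no phenology observations supplied")
  if (length(unique(observations$year)) < 10) {
    stop("need at least 10 observation years")
  }
  yrs <- observations$year
  wy <- lapply(yrs, function(y) {
    w <- weather[year_of(weather$date) == y, , drop = FALSE]
    if (!nrow(w)) stop("weather misses observation year ", y)
    w[order(doy_of(w$date)), ]
  })
  names(wy) <- as.character(yrs)

  # --- LU: grid over (t_base, exponent), inner search over f_crit -------
  obs_lu <- observations$lu_doy
  have_lu <- is.finite(obs_lu)
  if (all(obs_lu[have_lu] == obs_lu[have_lu][1])) {
    warning("all observed LU days identical; parameters weakly identified")
  }
  best <- list(rmse = Inf)
  for (tb in t_base_grid) for (ex in exponent_grid) {
    p <- template; p$t_base <- tb; p$photo_exponent <- ex
    cums <- lapply(which(have_lu), function(i) {
      w <- wy[[i]]
      doy <- doy_of(w$date)
      use <- doy >= p$forcing_start_doy
      cumsum(forcing_series(w$tmean[use], doy[use], latitude, p))
    })
    doys <- lapply(which(have_lu), function(i) {
      doy <- doy_of(wy[[i]]$date)
      doy[doy >= p$forcing_start_doy]
    })
    # candidate thresholds: cumulative forcing at each observed event day
    cand <- unlist(lapply(seq_along(cums), function(j) {
      k <- match(obs_lu[have_lu][j], doys[[j]])
      if (is.na(k)) NULL else cums[[j]][k]
    }))
    cand <- sort(unique(cand[cand > 0]))
    if (!length(cand)) next
    for (fc in cand) {
      pred <- vapply(seq_along(cums), function(j) {
        hit <- which(cums[[j]] >= fc)
        if (!length(hit)) 400 else doys[[j]][hit[1]] # heavy penalty for no-LU
      }, numeric(1))
      rmse <- sqrt(mean((pred - obs_lu[have_lu])^2))
      if (rmse < best$rmse - 1e-12) {
        best <- list(rmse = rmse, t_base = tb, exponent = ex, f_crit = fc)
      }
    }
  }
  if (!is.finite(best$rmse)) stop("LU model fit failed: no feasible threshold")

  # --- LC: OLS on the two window mean temperatures ----------------------
  obs_lc <- observations$lc_doy
  have_lc <- is.finite(obs_lc)
  tmat <- t(vapply(which(have_lc), function(i) {
    w <- wy[[i]]
    doy <- doy_of(w$date)
    c(ts = mean(w$tmean[doy >= template$spring_window[1] &
                          doy <= template$spring_window[2]]),
      ta = mean(w$tmean[doy >= template$summer_window[1] &
                          doy <= template$summer_window[2]]))
  }, numeric(2)))
  lcfit <- lm(obs_lc[have_lc] ~ tmat[, "ts"] + tmat[, "ta"])
  cs <- max(0, -coef(lcfit)[2])
  ca <- max(0, coef(lcfit)[3])
  if (cs == 0 || ca == 0) {
    # refit intercept with the clipped slopes
    ic <- mean(obs_lc[have_lc] + cs * tmat[, "ts"] - ca * tmat[, "ta"])
  } else {
    ic <- coef(lcfit)[1]
  }
  pred_lc <- ic - cs * tmat[, "ts"] + ca * tmat[, "ta"]
  rmse_lc <- sqrt(mean((pred_lc - obs_lc[have_lc])^2))

  params <- template
  params$t_base <- best$t_base
  params$photo_exponent <- best$exponent
  params$f_crit <- best$f_crit
  params$lc_intercept <- unname(ic)
  params$lc_coef_spring <- unname(cs)
  params$lc_coef_summer <- unname(ca)
  list(params = params, rmse_lu = best$rmse, rmse_lc = rmse_lc)
}
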