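# Species-specific age detrending of ring-width series: a hyperbolic
# juvenile term plus a softplus-smoothed linear transition to a plateau.
# The residual (observed minus age-expected width) is the climate signal
# carried forward to the sensitivity models.

#' Age-curve parameters
#'
#' The expected ring width at cambial age \eqn{a} is
#' \deqn{w_{age}(a) = p_n / a + p_s + w_{min} - 10 k \,
#'   \log(1 + e^{0.1 (p_m - a)})}
#' with the transition slope \eqn{k = (w_{min} - w_{50}) / (p_m - 50)}.
#' \code{w_50} is the width near age 50, \code{w_min} the assumed minimum
#' (old-age) ring width, \code{p_m} the transition age; as
#' \eqn{a \to \infty} the curve levels off at \eqn{p_s + w_{min}}.
#'
#' @param p_n hyperbolic juvenile coefficient, mm year.
#' @param p_s plateau offset, mm.
#' @param w_50 ring width near age 50, mm.
#' @param w_min assumed minimum ring width, mm (\code{w_min <= w_50}).
#' @param p_m transition age, years (> 50).
#' @param species optional species label.
#' @return an object of class \code{age_curve_params} with the derived
#'   slope \code{k}.
#' @export
age_curve_params <- function(p_n, p_s, w_50, w_min, p_m, species = NULL) {
  stopifnot(p_m > 50, w_min <= w_50, p_n >= 0, p_s >= 0, w_min >= 0)
  structure(list(p_n = p_n, p_s = p_s, w_50 = w_50, w_min = w_min,
                 p_m = p_m, k = (w_min - w_50) / (p_m - 50),
                 species = species),
            class = "age_curve_params")
}

#' @export
print.age_curve_params <- function(x, ...) {
  cat("<age_curve_params>", x$species %||% "", "\n")
  cat(sprintf("  p_n = %.3g, p_s = %.3g, w_50 = %.3g, w_min = %.3g, p_m = %.4g (k = %.5f)\n",
              x$p_n, x$p_s, x$w_50, x$w_min, x$p_m, x$k))
  invisible(x)
}

# overflow-safe softplus log(1 + exp(x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Expected ring width at a given cambial age
#'
#' @param age cambial age in years (> 0), vectorized.
#' @param params an [age_curve_params()].
#' @return expected ring width, mm.
#' @export
age_curve <- function(age, params) {
  stopifnot(inherits(params, "age_curve_params"))
  if (any(age <= 0)) stop("age must be positive")
  params$p_n / age + params$p_s + params$w_min -
    10 * params$k * softplus(0.1 * (params$p_m - age))
}

#' Fit the age curve to per-age mean ring widths
#'
#' The target of the fit is the mean ring width per cambial age assembled
#' across all trees of one species. The minimum ring width \code{w_min} is
#' an assumption, not a fitted parameter: the curve only depends on the
#' plateau level \eqn{p_s + w_{min}} and the transition slope, so fitting
#' all five parameters would be non-identifiable. By default \code{w_min}
#' is taken as the smallest observed per-age mean width. The remaining
#' four parameters are estimated by bounded Levenberg-Marquardt nonlinear
#' least squares, started from several transition ages to avoid local
#' minima; the best-RSS converged fit is returned with r-squared
#' statistics computed on the per-age mean series.
#'
#' @param age,width numeric vectors: distinct cambial ages and the mean
#'   ring width at each (mm). Alternatively \code{age} may be a data frame
#'   with columns \code{age} and \code{width}.
#' @param species optional label stored on the result.
#' @param w_min assumed minimum ring width, mm; default: smallest
#'   observed mean width.
#' @param pm_starts starting values for the transition age.
#' @return list with \code{params} ([age_curve_params()]), \code{r2},
#'   \code{adj_r2}, \code{rss}, \code{n}, \code{flat} (TRUE when the fitted
#'   transition slope is negligible).
#' @export
fit_age_curve <- function(age, width = NULL, species = NULL, w_min = NULL,
                          pm_starts = c(80, 120, 160, 220)) {
  if (is.data.frame(age)) { width <- age$width; age <- age$age }
  ok <- is.finite(age) & is.finite(width)
  age <- age[ok]; width <- width[ok]
  if (length(unique(age)) < 20) stop("need at least 20 distinct ages")
  o <- order(age); age <- age[o]; width <- width[o]

  w_min <- w_min %||% max(0, min(width))
  if (sd(width) < 1e-10) { # perfectly flat series: curve is the constant
    params <- age_curve_params(0, 0, width[1], width[1], 100,
                               species = species)
    return(list(params = params, r2 = NA_real_, adj_r2 = NA_real_,
                rss = 0, n = length(age), flat = TRUE))
  }
  d <- data.frame(age = age, width = width, w_min = w_min)
  w50_init <- mean(width[abs(age - 50) <= 10])
  if (!is.finite(w50_init)) w50_init <- mean(width)
  w50_init <- max(w50_init, w_min + 1e-6)
  pn_init <- max(0.1, (width[1] - w50_init) * age[1])

  model <- width ~ p_n / age + p_s + w_min -
    10 * ((w_min - w_50) / (p_m - 50)) * softplus(0.1 * (p_m - age))
  fits <- list()
  for (pm0 in pm_starts) {
    st <- list(p_n = pn_init, p_s = 0.01, w_50 = w50_init, p_m = pm0)
    f <- try(minpack.lm::nlsLM(
      model, data = d, start = st,
      lower = c(p_n = 0, p_s = 0, w_50 = w_min, p_m = 51),
      upper = c(p_n = 500, p_s = 20, w_50 = 20, p_m = 500),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) {
    stop("age-curve fit failed to converge from all starting values")
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  params <- age_curve_params(cf[["p_n"]], cf[["p_s"]], cf[["w_50"]],
                             w_min, cf[["p_m"]], species = species)
  pred <- age_curve(age, params)
  rss_b <- sum((width - pred)^2)
  tss <- sum((width - mean(width))^2)
  n <- length(age); p <- 4 # w_min is assumed, not estimated
  r2 <- if (tss > 0) 1 - rss_b / tss else NA_real_
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  list(params = params, r2 = r2, adj_r2 = adj, rss = rss_b, n = n,
       flat = abs(params$k) < 1e-6)
}

#' Detrend ring series with a fitted age curve
#'
#' Adds the age-expected width \code{w_age} and the residual
#' \code{w_res = w_obs - w_age} to a ring table. Rows with missing age are
#' dropped with a message.
#'
#' @param rings data frame with at least \code{age} and \code{w_obs} (mm);
#'   typically also species, site_id, tree_id, year.
#' @param params an [age_curve_params()], or a named list of them keyed by
#'   species when \code{rings$species} is present.
#' @return rings with columns \code{w_age} and \code{w_res} appended.
#' @export
detrend_rings <- function(rings, params) {
  drop <- !is.finite(rings$age)
  if (any(drop)) {
    message(sum(drop), " ring(s) without age skipped")
    rings <- rings[!drop, , drop = FALSE]
  }
  if (inherits(params, "age_curve_params")) {
    rings$w_age <- age_curve(rings$age, params)
  } else {
    stopifnot(!is.null(rings$species))
    miss <- setdiff(unique(rings$species), names(params))
    if (length(miss)) stop("no age-curve parameters for species: ",
                           paste(miss, collapse = ", "))
    rings$w_age <- NA_real_
    for (sp in unique(rings$species)) {
      i <- rings$species == sp
      rings$w_age[i] <- age_curve(rings$age[i], params[[sp]])
    }
  }
  rings$w_res <- rings$w_obs - rings$w_age
  rings
}
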