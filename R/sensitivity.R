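# Climate-growth sensitivity: Pearson screening of ring-width residuals
# against seasonal growth factors, collinearity preselection (one water
# factor plus temperature per season/lag), mixed-effects fitting with a
# site random intercept, and backward elimination by ML AIC.

#' Pearson screen of residuals against growth factors
#'
#' Correlates the site-year mean ring-width residual with every
#' standardized growth factor over all legal (season, lag) keys.
#'
#' @param residuals data frame with \code{site_id}, \code{year} (growth
#'   year) and \code{w_res} (tree-level rows are averaged per site-year).
#' @param factors standardized factor records (see
#'   [standardize_factors()]).
#' @param min_n minimum overlapping site-years per cell.
#' @return data frame: factor, season, lag, r, n; \code{r} is NA for
#'   constant factors or insufficient overlap.
#' @export
correlation_screen <- function(residuals, factors, min_n = 10) {
  rkey <- paste(residuals$site_id, residuals$year, sep = "\r")
  ukey <- unique(rkey)
  g <- match(rkey, ukey)
  rmean_val <- as.numeric(rowsum(residuals$w_res, g) / tabulate(g))

  keys <- legal_season_keys()
  grid <- merge(data.frame(factor = growth_factor_levels()), keys,
                sort = FALSE)
  gkey <- paste(grid$factor, grid$season, grid$lag, sep = "\r")
  fkey <- paste(factors$factor, factors$season, factors$lag, sep = "\r")
  frow <- paste(factors$site_id, factors$growth_year, sep = "\r")
  m <- matrix(NA_real_, nrow = length(ukey), ncol = length(gkey))
  sel <- fkey %in% gkey & frow %in% ukey
  m[cbind(match(frow[sel], ukey), match(fkey[sel], gkey))] <-
    factors$std_value[sel]

  r <- rep(NA_real_, length(gkey))
  n <- integer(length(gkey))
  for (i in seq_along(gkey)) {
    ok <- !is.na(m[, i])
    n[i] <- sum(ok)
    if (n[i] >= min_n && sd(m[ok, i]) > 1e-12 &&
        sd(rmean_val[ok]) > 1e-12) {
      r[i] <- cor(m[ok, i], rmean_val[ok])
    }
  }
  data.frame(factor = grid$factor, season = grid$season, lag = grid$lag,
             r = r, n = n)
}

#' Preselect model candidates from the correlation screen
#'
#' For each legal (season, lag) key, keeps the water-category factor with
#' the largest absolute correlation (ties broken by the canonical factor
#' order) plus mean temperature — at most 2 x 14 = 28 candidates.
#'
#' @param screen output of [correlation_screen()].
#' @return data frame: factor, season, lag, r, term.
#' @export
preselect_candidates <- function(screen) {
  keys <- legal_season_keys()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    s <- keys$season[i]; l <- keys$lag[i]
    cell <- screen[screen$season == s & screen$lag == l, , drop = FALSE]
    water <- cell[cell$factor %in% water_factor_levels() &
                    is.finite(cell$r), , drop = FALSE]
    if (nrow(water)) {
      ord <- order(-abs(water$r), match(water$factor, water_factor_levels()))
      rows[[length(rows) + 1]] <- water[ord[1], , drop = FALSE]
    }
    temp <- cell[cell$factor == "mean_temp" & is.finite(cell$r), ,
                 drop = FALSE]
    if (nrow(temp)) rows[[length(rows) + 1]] <- temp
    if (!nrow(water) && !nrow(temp)) {
      message("season (", s, ", ", l, ") dropped: no usable factor")
    }
  }
  out <- do.call(rbind, rows)
  out$term <- term_name(out$factor, out$season, out$lag)
  rownames(out) <- NULL
  out[, c("factor", "season", "lag", "r", "term")]
}

# assemble the modelling frame: response + candidate term columns
build_model_frame <- function(residuals, factors, terms,
                              response = c("tree", "site_mean")) {
  response <- match.arg(response)
  if (response == "site_mean") {
    residuals <- aggregate(w_res ~ site_id + year, data = residuals,
                           FUN = mean)
  }
  wide <- factors_wide(factors)
  keep <- c("site_id", "growth_year", terms)
  miss <- setdiff(terms, names(wide))
  if (length(miss)) stop("factors miss candidate term(s): ",
                         paste(miss, collapse = ", "))
  wide <- wide[, keep, drop = FALSE]
  mf <- merge(residuals, wide,
              by.x = c("site_id", "year"),
              by.y = c("site_id", "growth_year"))
  mf <- mf[complete.cases(mf[, c("w_res", terms)]), , drop = FALSE]
  if (!nrow(mf)) stop("no overlapping residual/factor rows")
  mf$site_id <- factor(mf$site_id)
  mf
}

#' Fit the climate-growth sensitivity model
#'
#' Linear mixed-effects model of ring-width residuals on the candidate
#' standardized growth factors, with a site random intercept, estimated by
#' maximum likelihood (for AIC comparability) and refitted by REML for the
#' reported estimates. Species present at a single site fall back to
#' ordinary least squares, as a random site intercept is then not
#' identifiable.
#'
#' @param residuals data frame: \code{site_id}, \code{year}, \code{w_res}
#'   (and optionally \code{species}).
#' @param factors standardized factor records.
#' @param candidates data frame from [preselect_candidates()] (or any
#'   table with a \code{term} column / character vector of terms).
#' @param response \code{"tree"}: individual tree-year residuals (default);
#'   \code{"site_mean"}: site-year mean residuals.
#' @param species optional label.
#' @return an object of class \code{sensitivity_model}: retained terms with
#'   estimates, standard errors and Wald p-values, intercept, variance
#'   components, ML AIC and log-likelihood, r-squared decomposition.
#' @export
fit_sensitivity <- function(residuals, factors, candidates,
                            response = c("tree", "site_mean"),
                            species = NULL) {
  response <- match.arg(response)
  terms <- if (is.character(candidates)) candidates else candidates$term
  if (length(terms) < 1) stop("need at least one candidate term")
  mf <- build_model_frame(residuals, factors, terms, response)
  refit_sensitivity(mf, terms, species = species, response = response)
}

# fit on an already-built model frame (used by the stepwise search)
refit_sensitivity <- function(mf, terms, species = NULL,
                              response = "tree") {
  single_site <- length(unique(mf$site_id)) < 2
  fml <- as.formula(paste("w_res ~",
                          if (length(terms)) paste(terms, collapse = " + ")
                          else "1"))
  note <- NULL
  if (single_site) {
    fit <- lm(fml, data = mf)
    sm <- summary(fit)$coefficients
    est <- data.frame(term = rownames(sm)[-1],
                      estimate = sm[-1, 1], se = sm[-1, 2], p = sm[-1, 4])
    intercept <- sm[1, 1]
    site_sd <- NA_real_
    resid_sd <- summary(fit)$sigma
    aic_ml <- AIC(fit)
    ll <- as.numeric(logLik(fit))
    note <- "single site: ordinary least squares, no random intercept"
    fixed_pred <- fitted(fit)
  } else {
    fit_ml <- tryCatch(
      nlme::lme(fml, random = ~ 1 | site_id, data = mf, method = "ML",
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE)),
      error = function(e) NULL)
    if (is.null(fit_ml)) { # singular / failed: drop the random effect
      fit <- lm(fml, data = mf)
      sm <- summary(fit)$coefficients
      est <- data.frame(term = rownames(sm)[-1],
                        estimate = sm[-1, 1], se = sm[-1, 2], p = sm[-1, 4])
      intercept <- sm[1, 1]
      site_sd <- 0
      resid_sd <- summary(fit)$sigma
      aic_ml <- AIC(fit)
      ll <- as.numeric(logLik(fit))
      note <- "random-intercept fit singular: refitted without it"
      fixed_pred <- fitted(fit)
      rownames(est) <- NULL
      obj <- structure(list(
        species = species, terms = terms, estimates = est,
        intercept = unname(intercept), site_sd = site_sd,
        resid_sd = resid_sd, aic = aic_ml, loglik = ll,
        n = nrow(mf), n_sites = length(unique(mf$site_id)),
        response = response, data = mf, fit = fit, note = note),
        class = "sensitivity_model")
      r2 <- r2_decomposition(obj, fixed_pred = fixed_pred)
      obj$marginal_r2 <- r2$marginal_r2
      obj$conditional_r2 <- r2$conditional_r2
      return(obj)
    }
    aic_ml <- AIC(fit_ml)
    ll <- as.numeric(logLik(fit_ml))
    fit <- nlme::lme(fml, random = ~ 1 | site_id, data = mf,
                     method = "REML",
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
    tt <- summary(fit)$tTable
    est <- data.frame(term = rownames(tt)[-1],
                      estimate = tt[-1, "Value"],
                      se = tt[-1, "Std.Error"],
                      p = tt[-1, "p-value"])
    intercept <- tt[1, "Value"]
    vc <- nlme::VarCorr(fit)
    site_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    resid_sd <- fit$sigma
    fixed_pred <- predict(fit, level = 0)
  }
  rownames(est) <- NULL
  obj <- structure(list(
    species = species, terms = terms, estimates = est,
    intercept = unname(intercept), site_sd = site_sd,
    resid_sd = resid_sd, aic = aic_ml, loglik = ll,
    n = nrow(mf), n_sites = length(unique(mf$site_id)),
    response = response, data = mf, fit = fit, note = note),
    class = "sensitivity_model")
  r2 <- r2_decomposition(obj, fixed_pred = fixed_pred)
  obj$marginal_r2 <- r2$marginal_r2
  obj$conditional_r2 <- r2$conditional_r2
  obj
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat("<sensitivity_model>", x$species %||% "", "\n")
  cat(sprintf("  %d obs, %d site(s), response = %s\n",
              x$n, x$n_sites, x$response))
  cat(sprintf("  ML AIC = %.2f | site sd = %s mm | resid sd = %.3f mm\n",
              x$aic,
              if (is.na(x$site_sd)) "-" else sprintf("%.3f", x$site_sd),
              x$resid_sd))
  cat(sprintf("  marginal r2 = %.3f, conditional r2 = %s\n",
              x$marginal_r2,
              if (is.na(x$conditional_r2)) "-"
              else sprintf("%.3f", x$conditional_r2)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  cat(sprintf("  intercept = %.4f mm + %d term(s):\n",
              x$intercept, nrow(x$estimates)))
  if (nrow(x$estimates)) {
    df <- x$estimates
    df$estimate <- round(df$estimate, 5)
    df$p <- signif(df$p, 3)
    print(df[, c("term", "estimate", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' Backward elimination by AIC
#'
#' Starting from the full candidate model, repeatedly removes the single
#' term whose removal lowers the ML AIC the most, stopping when no removal
#' lowers it. The intercept is never removed. Candidate scans use an exact
#' profiled-likelihood evaluation of the random-intercept model; the
#' returned model is refitted with the standard engine.
#'
#' @param model a [fit_sensitivity()] result (the full model).
#' @return a \code{sensitivity_model} for the retained terms, with an
#'   attribute \code{"path"} recording the removal order.
#' @export
stepwise_aic <- function(model) {
  stopifnot(inherits(model, "sensitivity_model"))
  mf <- model$data
  terms <- model$terms
  grp <- if (model$n_sites >= 2) mf$site_id else NULL
  y <- mf$w_res
  Xfull <- cbind(`(Intercept)` = 1,
                 as.matrix(mf[, terms, drop = FALSE]))
  st <- ml_ri_stats(y, Xfull, grp)
  hint <- NULL
  aic_of <- function(keep) {
    iv <- if (is.null(hint)) c(-14, 10) else hint + c(-2, 2)
    # the profile is flat near its optimum: a coarse lambda suffices for
    # AIC comparisons at far better than 1e-4 accuracy
    ml_ri_fit_xtx(st, c(1L, 1L + keep), interval = iv, tol = 1e-3)
  }
  keep <- seq_along(terms)
  fit0 <- aic_of(keep)
  current <- fit0$aic
  if (!is.null(grp)) hint <- log(max(fit0$lambda, 1e-6))
  path <- character()
  while (length(keep) > 0) {
    cand_aic <- vapply(seq_along(keep), function(j) {
      aic_of(keep[-j])$aic
    }, numeric(1))
    j <- which.min(cand_aic) # ties: first in candidate order
    if (cand_aic[j] < current) {
      path <- c(path, terms[keep[j]])
      keep <- keep[-j]
      current <- cand_aic[j]
    } else break
  }
  out <- refit_sensitivity(mf, terms[keep], species = model$species,
                           response = model$response)
  attr(out, "path") <- path
  out
}

#' Marginal and conditional r-squared of a sensitivity model
#'
#' Variance-decomposition r-squared for mixed models: marginal r2 is the
#' fixed-effect share of the total variance (fixed + random intercept +
#' residual); conditional r2 adds the site random-intercept share.
#' Single-site models report a missing conditional r2.
#'
#' @param model a \code{sensitivity_model}.
#' @param fixed_pred optional precomputed fixed-effect predictions.
#' @return list with \code{marginal_r2} and \code{conditional_r2}.
#' @export
r2_decomposition <- function(model, fixed_pred = NULL) {
  stopifnot(inherits(model, "sensitivity_model"))
  if (is.null(fixed_pred)) {
    X <- as.matrix(model$data[, model$terms, drop = FALSE])
    fixed_pred <- model$intercept +
      if (length(model$terms)) drop(X %*% model$estimates$estimate) else 0
  }
  var_f <- if (length(fixed_pred) > 1) var(fixed_pred) else 0
  if (length(model$terms) == 0) var_f <- 0
  var_b <- if (is.na(model$site_sd)) 0 else model$site_sd^2
  var_e <- model$resid_sd^2
  tot <- var_f + var_b + var_e
  marginal <- var_f / tot
  conditional <- if (model$n_sites < 2 || is.na(model$site_sd)) {
    NA_real_
  } else {
    (var_f + var_b) / tot
  }
  list(marginal_r2 = marginal, conditional_r2 = conditional)
}
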