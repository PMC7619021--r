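# Correlation screening, preselection, mixed-effects fitting and
# backward AIC elimination.

# shared small experiment: 4 sites, two planted coefficients
fx_experiment <- function() {
  fx_memo("experiment", function() {
    std <- fx_factors()
    p <- fx_fagus_age_params()
    beta <- data.frame(
      factor = c("mean_soil_moisture", "mean_temp"),
      season = c("JunJul", "JunJul"), lag = c("act", "act"),
      beta = c(0.09, -0.10))
    tr <- ring_truth(p, beta, site_intercept_sd = 0.15, residual_sd = 0.3,
                     n_sites = 4, trees_per_site = 7, seed = 9)
    rings <- generate_ring_series(tr, std$records)
    resid <- detrend_rings(rings, p)
    list(std = std, resid = resid, beta = beta, truth = tr)
  })
}

test_that("the profiled-ML fitter agrees with nlme on the ML scale", {
  set.seed(42)
  d <- expand.grid(site = factor(1:12), year = 1:30)
  X <- matrix(rnorm(nrow(d) * 4), ncol = 4)
  colnames(X) <- paste0("x", 1:4)
  d <- cbind(d, X)
  d$y <- 0.1 * d$x1 - 0.08 * d$x2 +
    rnorm(12, 0, 0.12)[as.integer(d$site)] + rnorm(nrow(d), 0, 0.3)
  ref <- nlme::lme(y ~ x1 + x2 + x3 + x4, random = ~ 1 | site, data = d,
                   method = "ML")
  fast <- ringclim:::ml_ri_fit(d$y, cbind(1, X), d$site)
  expect_equal(fast$aic, AIC(ref), tolerance = 1e-7)
  expect_equal(unname(fast$beta), unname(nlme::fixef(ref)),
               tolerance = 1e-6)
  # zero site variance collapses to OLS
  d$y0 <- 0.1 * d$x1 + rnorm(nrow(d), 0, 0.3)
  fast0 <- ringclim:::ml_ri_fit(d$y0, cbind(1, X), d$site)
  ols <- lm(y0 ~ x1 + x2 + x3 + x4, data = d)
  expect_lt(fast0$sigma2_b, 1e-4)
  expect_equal(unname(fast0$beta), unname(coef(ols)), tolerance = 1e-4)
})

test_that("the screen finds the planted factor and matches duplicates", {
  ex <- fx_experiment()
  scr <- correlation_screen(ex$resid, ex$std$records)
  expect_equal(nrow(scr), 7 * 14)
  cell <- scr[scr$factor == "mean_soil_moisture" & scr$season == "JunJul" &
                scr$lag == "act", ]
  expect_gt(cell$r, 0.2)
  tcell <- scr[scr$factor == "mean_temp" & scr$season == "JunJul" &
                 scr$lag == "act", ]
  expect_lt(tcell$r, -0.2)
  # among water factors in that cell the planted one has the largest |r|
  water <- scr[scr$season == "JunJul" & scr$lag == "act" &
                 scr$factor != "mean_temp", ]
  expect_equal(water$factor[which.max(abs(water$r))],
               "mean_soil_moisture")
  # a duplicated factor (same values under a different name) gets the same r
  recs <- ex$std$records
  dup <- recs[recs$factor == "mean_temp", ]
  dup$factor <- "transp_sum"
  scr2 <- correlation_screen(ex$resid,
                             rbind(recs[recs$factor != "transp_sum", ], dup))
  a <- scr2[scr2$factor == "mean_temp", c("season", "lag", "r")]
  b <- scr2[scr2$factor == "transp_sum", c("season", "lag", "r")]
  expect_equal(a$r, b$r[match(paste(a$season, a$lag),
                              paste(b$season, b$lag))])
})

test_that("pure-noise residuals stay inside the permutation null envelope", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = character(), season = character(),
                                 lag = character(), beta = numeric()),
                   site_intercept_sd = 0, residual_sd = 0.3,
                   n_sites = 4, trees_per_site = 7, seed = 77)
  resid <- detrend_rings(generate_ring_series(tr, std$records), p)
  scr <- correlation_screen(resid, std$records)
  observed_max <- max(abs(scr$r), na.rm = TRUE)
  # permutation oracle: break the year link within sites
  set.seed(13)
  null_max <- replicate(100, {
    shuffled <- resid
    for (s in unique(shuffled$site_id)) {
      i <- shuffled$site_id == s
      yrs <- unique(shuffled$year[i])
      map <- setNames(sample(yrs), yrs)
      shuffled$year[i] <- map[as.character(shuffled$year[i])]
    }
    max(abs(correlation_screen(shuffled, std$records)$r), na.rm = TRUE)
  })
  expect_lt(observed_max, quantile(null_max, 0.99) + 0.05)
})

test_that("preselection keeps one water factor plus temperature per key", {
  ex <- fx_experiment()
  scr <- correlation_screen(ex$resid, ex$std$records)
  cand <- preselect_candidates(scr)
  expect_lte(nrow(cand), 28)
  expect_equal(nrow(legal_season_keys()), 14)
  per_key <- table(paste(cand$season, cand$lag),
                   cand$factor == "mean_temp")
  expect_true(all(per_key <= 1)) # one water + one temperature per key
  expect_true("mean_soil_moisture_JunJul_act" %in% cand$term)
  # deterministic under ties: a constructed tie resolves by factor order
  tie <- data.frame(factor = c("transp_deficit", "climatic_wb"),
                    season = "JunJul", lag = "act", r = c(0.5, 0.5), n = 30)
  got <- suppressMessages(preselect_candidates(tie))
  # the canonical factor order puts climatic_wb before transp_deficit
  expect_equal(got$factor[1], "climatic_wb")
})

test_that("the mixed model recovers planted coefficients and site variance", {
  ex <- fx_experiment()
  m <- fit_sensitivity(ex$resid, ex$std$records,
                       c("mean_soil_moisture_JunJul_act",
                         "mean_temp_JunJul_act"),
                       species = "Fagus sylvatica")
  est <- m$estimates
  for (j in 1:2) {
    i <- match(paste0(ex$beta$factor[j], "_JunJul_act"), est$term)
    expect_lt(abs(est$estimate[i] - ex$beta$beta[j]), 2.5 * est$se[i])
  }
  # with only 4 sites the site-sd estimate is noisy; just require a
  # positive, bounded estimate
  expect_gt(m$site_sd, 0.005)
  expect_lt(m$site_sd, 0.5)
  expect_lt(abs(m$resid_sd - 0.3), 0.03)
  expect_gte(m$conditional_r2, m$marginal_r2)
  # refit on a row-permuted copy returns identical estimates
  set.seed(3)
  shuf <- ex$resid[sample(nrow(ex$resid)), ]
  m2 <- fit_sensitivity(shuf, ex$std$records,
                        c("mean_soil_moisture_JunJul_act",
                          "mean_temp_JunJul_act"))
  expect_equal(sort(m2$estimates$estimate), sort(est$estimate),
               tolerance = 1e-8)
})

test_that("coefficients are invariant to raw-factor rescaling", {
  ex <- fx_experiment()
  rescaled_raw <- ex$std$raw
  i <- rescaled_raw$factor == "mean_soil_moisture"
  rescaled_raw$raw_value[i] <- rescaled_raw$raw_value[i] * 1000
  lag <- suppressMessages(attach_lags(rescaled_raw))
  std2 <- suppressWarnings(standardize_factors(lag,
                                               reference = c(1962, 2000)))
  m1 <- fit_sensitivity(ex$resid, ex$std$records,
                        c("mean_soil_moisture_JunJul_act",
                          "mean_temp_JunJul_act"))
  m2 <- fit_sensitivity(ex$resid, std2$records,
                        c("mean_soil_moisture_JunJul_act",
                          "mean_temp_JunJul_act"))
  expect_equal(m1$estimates$estimate, m2$estimates$estimate,
               tolerance = 1e-8)
})

test_that("a zero-variance site effect is estimated near zero", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = "mean_temp", season = "JunJul",
                                 lag = "act", beta = -0.1),
                   site_intercept_sd = 0, residual_sd = 0.3,
                   n_sites = 4, trees_per_site = 7, seed = 31)
  resid <- detrend_rings(generate_ring_series(tr, std$records), p)
  m <- fit_sensitivity(resid, std$records, "mean_temp_JunJul_act")
  expect_lt(m$site_sd, 0.05)
})

test_that("single-site data fall back to ordinary least squares", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = "mean_temp", season = "JunJul",
                                 lag = "act", beta = -0.15),
                   site_intercept_sd = 0, residual_sd = 0.3,
                   n_sites = 1, trees_per_site = 7, seed = 33)
  resid <- detrend_rings(generate_ring_series(tr, std$records), p)
  m <- fit_sensitivity(resid, std$records, "mean_temp_JunJul_act",
                       species = "one-site")
  expect_match(m$note, "single site")
  expect_true(is.na(m$conditional_r2))
  expect_false(is.na(m$marginal_r2))
})

test_that("backward elimination lowers AIC and keeps planted terms", {
  ex <- fx_experiment()
  scr <- correlation_screen(ex$resid, ex$std$records)
  cand <- preselect_candidates(scr)
  full <- fit_sensitivity(ex$resid, ex$std$records, cand,
                          species = "Fagus sylvatica")
  red <- stepwise_aic(full)
  expect_lte(red$aic, full$aic)
  expect_true(all(c("mean_soil_moisture_JunJul_act",
                    "mean_temp_JunJul_act") %in% red$estimates$term))
  expect_true(all(red$estimates$term %in% cand$term))
  # deterministic: same input, same path
  red2 <- stepwise_aic(full)
  expect_identical(attr(red, "path"), attr(red2, "path"))
  expect_equal(red$estimates$estimate, red2$estimates$estimate)
})

test_that("pure-noise response with few candidates keeps the intercept only", {
  std <- fx_factors()
  p <- fx_fagus_age_params()
  cand3 <- c("mean_temp_JanMar_m2", "climatic_wb_AprMay_m1",
             "mean_soil_moisture_AugSep_act")
  set.seed(17)
  sizes <- replicate(25, {
    tr <- ring_truth(p, data.frame(factor = character(),
                                   season = character(), lag = character(),
                                   beta = numeric()),
                     site_intercept_sd = 0.1, residual_sd = 0.3,
                     n_sites = 4, trees_per_site = 7,
                     seed = sample.int(1e6, 1))
    resid <- detrend_rings(generate_ring_series(tr, std$records), p)
    m <- fit_sensitivity(resid, std$records, cand3)
    nrow(stepwise_aic(m)$estimates)
  })
  # intercept-only is the modal outcome under the null
  expect_gte(sum(sizes == 0), max(table(sizes[sizes > 0]), 0))
  expect_gt(mean(sizes == 0), 0.4)
})

test_that("r2 decomposition splits fixed and site variance", {
  ex <- fx_experiment()
  m <- fit_sensitivity(ex$resid, ex$std$records,
                       c("mean_soil_moisture_JunJul_act",
                         "mean_temp_JunJul_act"))
  r2 <- r2_decomposition(m)
  expect_gt(r2$marginal_r2, 0)
  expect_gte(r2$conditional_r2, r2$marginal_r2)
  # a site-only signal: marginal ~ 0 < conditional
  std <- fx_factors()
  p <- fx_fagus_age_params()
  tr <- ring_truth(p, data.frame(factor = character(), season = character(),
                                 lag = character(), beta = numeric()),
                   site_intercept_sd = 0.3, residual_sd = 0.3,
                   n_sites = 4, trees_per_site = 7, seed = 55)
  resid <- detrend_rings(generate_ring_series(tr, std$records), p)
  m0 <- fit_sensitivity(resid, std$records, "mean_temp_JanMar_m1")
  r20 <- r2_decomposition(m0)
  expect_lt(r20$marginal_r2, 0.05)
  expect_gt(r20$conditional_r2, r20$marginal_r2 + 0.1)
})
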