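# Fast exact maximum-likelihood fitter for the linear model with a single
# random intercept. Used inside the backward-elimination scan, where
# hundreds of candidate fixed-effect subsets must be compared on the ML
# AIC scale; its likelihood agrees with nlme/lme4 to optimizer tolerance
# (asserted in the test suite).
#
# Model: y = X beta + b_g + e, b_g ~ N(0, s2_b), e ~ N(0, s2_e).
# With lambda = s2_b / s2_e, V = I + lambda Z Z'. GLS reduces to OLS on
# partially group-demeaned data (demeaning weight 1 - 1/sqrt(1 + n_g
# lambda)); the profile log-likelihood over (beta, s2_e) is maximized in
# the single parameter log(lambda).

ml_ri_profile <- function(loglam, y, X, gidx, gn, ybar_g, Xbar_g) {
  lam <- exp(loglam)
  w <- 1 - 1 / sqrt(1 + gn * lam)
  yt <- y - (w[gidx] * ybar_g[gidx])
  Xt <- X - (w[gidx] * Xbar_g[gidx, , drop = FALSE])
  fit <- .lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  ldet <- sum(log1p(gn * lam))
  -(n / 2) * (log(2 * pi * rss / n) + 1) - ldet / 2
}

# y: response; X: design matrix (with intercept column); group: factor-like
# `interval` brackets the search for log(lambda); it is widened
# automatically when the optimum lands on an interior edge.
ml_ri_fit <- function(y, X, group = NULL, interval = c(-14, 10),
                      tol = 1e-7) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(group)) { # plain OLS, ML scale
    fit <- .lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    return(list(loglik = ll, aic = -2 * ll + 2 * (p + 1),
                beta = fit$coefficients, sigma2 = rss / n,
                lambda = 0, sigma2_b = 0, df = p + 1))
  }
  g <- as.integer(factor(group))
  gn <- tabulate(g)
  ybar_g <- as.numeric(rowsum(y, g) / gn)
  Xbar_g <- rowsum(X, g) / gn

  f <- function(ll) -ml_ri_profile(ll, y, X, g, gn, ybar_g, Xbar_g)
  lo <- max(interval[1], -14); hi <- min(interval[2], 10)
  repeat {
    opt <- optimize(f, c(lo, hi), tol = tol)
    widened <- FALSE
    if (opt$minimum < lo + 0.25 && lo > -14) {
      lo <- max(-14, lo - 3); widened <- TRUE
    }
    if (opt$minimum > hi - 0.25 && hi < 10) {
      hi <- min(10, hi + 3); widened <- TRUE
    }
    if (!widened) break
  }
  # the boundary lambda -> 0 (no site variance) must not be missed
  ll0 <- if (lo <= -14) -f(-14) else -Inf
  if (ll0 >= -opt$objective - 1e-10) {
    loglam <- -14
    ll <- ll0
  } else {
    loglam <- opt$minimum
    ll <- -opt$objective
  }
  lam <- exp(loglam)
  w <- 1 - 1 / sqrt(1 + gn * lam)
  yt <- y - (w[g] * ybar_g[g])
  Xt <- X - (w[g] * Xbar_g[g, , drop = FALSE])
  fit <- .lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  list(loglik = ll, aic = -2 * ll + 2 * (p + 2),
       beta = fit$coefficients, sigma2 = sigma2,
       lambda = lam, sigma2_b = lam * sigma2, df = p + 2)
}

# -- cross-product fast path for the backward-elimination scan -----------
# The group-demeaned normal equations only involve X'X, X'y, y'y, the
# per-group means and counts: for weight w_g = 1 - 1/sqrt(1 + n_g lambda)
# and d_g = n_g w_g (2 - w_g),
#   Xt'Xt = X'X - M' diag(d) M,  Xt'y~ = X'y - M' (d * my),
#   y~'y~ = y'y - sum(d * my^2),
# so a lambda evaluation costs O(G p^2) regardless of n, and a candidate
# deletion is an index subset of the full-model cross-products.

ml_ri_stats <- function(y, X, group = NULL) {
  if (is.null(group)) {
    g <- NULL; gn <- NULL; M <- NULL; my <- NULL
  } else {
    g <- as.integer(factor(group))
    gn <- tabulate(g)
    M <- rowsum(X, g) / gn
    my <- as.numeric(rowsum(y, g) / gn)
  }
  list(S = crossprod(X), Xty = drop(crossprod(X, y)),
       yty = sum(y * y), M = M, my = my, gn = gn, n = length(y))
}

ml_ri_rss_xtx <- function(st, cols, d) {
  S <- st$S[cols, cols, drop = FALSE]
  b <- st$Xty[cols]
  yty <- st$yty
  if (!is.null(d)) {
    Mc <- st$M[, cols, drop = FALSE]
    S <- S - crossprod(Mc, d * Mc)
    b <- b - drop(crossprod(Mc, d * st$my))
    yty <- yty - sum(d * st$my^2)
  }
  beta <- tryCatch(drop(chol2inv(chol(S)) %*% b),
                   error = function(e) drop(qr.solve(S, b)))
  list(rss = max(yty - sum(beta * b), 1e-300), beta = beta)
}

ml_ri_fit_xtx <- function(st, cols, interval = c(-14, 10), tol = 1e-3) {
  n <- st$n
  p <- length(cols)
  if (is.null(st$gn)) {
    sol <- ml_ri_rss_xtx(st, cols, NULL)
    ll <- -(n / 2) * (log(2 * pi * sol$rss / n) + 1)
    return(list(loglik = ll, aic = -2 * ll + 2 * (p + 1),
                beta = sol$beta, lambda = 0))
  }
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 - 1 / sqrt(1 + st$gn * lam)
    d <- st$gn * w * (2 - w)
    rss <- ml_ri_rss_xtx(st, cols, d)$rss
    (n / 2) * (log(2 * pi * rss / n) + 1) + sum(log1p(st$gn * lam)) / 2
  }
  lo <- max(interval[1], -14); hi <- min(interval[2], 10)
  repeat {
    opt <- optimize(prof, c(lo, hi), tol = tol)
    widened <- FALSE
    if (opt$minimum < lo + 0.25 && lo > -14) {
      lo <- max(-14, lo - 3); widened <- TRUE
    }
    if (opt$minimum > hi - 0.25 && hi < 10) {
      hi <- min(10, hi + 3); widened <- TRUE
    }
    if (!widened) break
  }
  ll0 <- if (lo <= -14) -prof(-14) else -Inf
  if (ll0 >= -opt$objective - 1e-10) {
    loglam <- -14; ll <- ll0
  } else {
    loglam <- opt$minimum; ll <- -opt$objective
  }
  lam <- exp(loglam)
  w <- 1 - 1 / sqrt(1 + st$gn * lam)
  sol <- ml_ri_rss_xtx(st, cols, st$gn * w * (2 - w))
  list(loglik = ll, aic = -2 * ll + 2 * (p + 2), beta = sol$beta,
       lambda = lam)
}
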