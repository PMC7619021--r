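# Shared fixtures, built in code and memoized for the session.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, .fx_cache)) assign(key, builder(), .fx_cache)
  get(key, .fx_cache)
}

# one site's merged daily table (weather + water balance)
fx_daily <- function(seed = 11, start_year = 1990, end_year = 2000,
                     soil = soil_params(), physio = site_physio("S01")) {
  key <- paste("daily", seed, start_year, end_year)
  fx_memo(key, function() {
    w <- generate_weather(weather_config(start_year = start_year,
                                         end_year = end_year, seed = seed))
    wb <- run_water_balance(w, soil, physio)
    cbind(w[, c("date", "tmean", "precip")],
          wb[, c("t_act", "t_pot", "theta", "rew")])
  })
}

# standardized multi-site growth factors with frozen moments
fx_factors <- function(n_sites = 4, start_year = 1960, end_year = 2000,
                       seed0 = 100) {
  key <- paste("factors", n_sites, start_year, end_year, seed0)
  fx_memo(key, function() {
    sites <- sprintf("S%02d", seq_len(n_sites))
    raw <- do.call(rbind, lapply(seq_along(sites), function(i) {
      w <- generate_weather(weather_config(
        site_id = sites[i], start_year = start_year, end_year = end_year,
        seed = seed0 + i))
      wb <- run_water_balance(w, soil_params(), site_physio(sites[i]))
      daily <- cbind(w[, c("date", "tmean", "precip")],
                     wb[, c("t_act", "t_pot", "theta", "rew")])
      build_growth_factors(daily, sites[i])
    }))
    lag <- suppressMessages(attach_lags(raw))
    std <- suppressWarnings(
      standardize_factors(lag, reference = c(start_year + 2, end_year)))
    c(std, list(raw = raw))
  })
}

fx_fagus_age_params <- function() {
  age_curve_params(p_n = 2.3, p_s = 0, w_50 = 1.7, w_min = 0.9,
                   p_m = 218.5, species = "Fagus sylvatica")
}

# synthetic daily forcing for mass-balance property tests (not a weather
# table: raw driver vectors)
fx_random_forcing <- function(n, seed = 1) {
  set.seed(seed)
  list(precip = rgamma(n, 0.5, scale = 12) * rbinom(n, 1, 0.45),
       tmean = runif(n, -15, 30),
       et0 = runif(n, 0, 8),
       in_leaf = runif(n) < 0.6)
}
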