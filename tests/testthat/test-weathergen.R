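test_that("degenerate records produce degenerate but valid models", {
  # all-dry record
  dry <- daily_series("2001-01-01", rep(0, 730), rep(2, 730), rep(8, 730))
  m <- suppressWarnings(fit_weathergen(dry))
  sim <- simulate_daily(m, 3, seed = 1)
  expect_true(all(sim$precip_mm == 0))

  # every day wet with constant 5 mm: amounts are a point mass at 5
  wet <- daily_series("2001-01-01", rep(5, 730), rep(2, 730), rep(8, 730))
  mw <- fit_weathergen(wet)
  simw <- simulate_daily(mw, 3, seed = 1)
  expect_true(all(simw$precip_mm == 5))
})

test_that("a month with zero wet days warns and stays dry in simulation", {
  obs <- test_obs()
  p <- obs$precip_mm
  # zero out July by the record's real calendar (the generator groups
  # observed days by their actual month)
  mon <- as.integer(format(obs$start_date + seq_len(length(obs)) - 1, "%m"))
  p[mon == 7] <- 0
  obs_dry_july <- daily_series(obs$start_date, p, obs$tmin_c, obs$tmax_c)
  expect_warning(m <- fit_weathergen(obs_dry_july), "zero wet days")
  sim <- simulate_daily(m, 50, seed = 3)
  sim_mon <- rep_len(make_calendar(12)$interval_of_day, length(sim))
  # spells starting in other months may run into July, but July must be
  # almost entirely dry
  expect_lt(mean(sim$precip_mm[sim_mon == 7] > 0.1), 0.03)
})

test_that("simulation is deterministic under a fixed seed", {
  m <- test_model()
  a <- simulate_daily(m, 5, seed = 123)
  b <- simulate_daily(m, 5, seed = 123)
  expect_identical(a, b)
  c <- simulate_daily(m, 5, seed = 124)
  expect_false(identical(a$precip_mm, c$precip_mm))
})

test_that("simulated series satisfy the daily-series invariants", {
  m <- test_model()
  sim <- simulate_daily(m, 100, seed = 9)
  expect_true(all(sim$precip_mm >= 0))
  expect_true(all(sim$tmin_c <= sim$tmax_c))
  expect_length(sim, 100 * 365)
})

test_that("the fitted seasonal mean curve recovers a known sinusoid", {
  # fixture truth: the daily mean temperature curve is a pure sinusoid,
  # which lies exactly in the span of the order-3 Fourier basis, so the
  # fit error is pure sampling noise. The pointwise standard error of
  # the fitted curve follows from the basis leverage; the whole curve
  # must sit inside a 4-sigma band of the truth.
  params <- synth_weather_params()
  obs <- test_obs()
  m <- test_model()
  truth_mid <- params$mean_temp_c -
    params$seasonal_amp_c * cos(2 * pi * ((1:365) - 15) / 365)
  dates <- obs$start_date + seq_len(length(obs)) - 1
  d365 <- holoclim:::doy365(dates)
  wet <- obs$precip_mm > 0.1
  B <- holoclim:::fourier_basis(1:365)
  for (cond in c("wet", "dry")) {
    fitted_mid <- (holoclim:::eval_fourier(m$tmin[[cond]]$mu_coef) +
                   holoclim:::eval_fourier(m$tmax[[cond]]$mu_coef)) / 2
    X <- holoclim:::fourier_basis(d365[wet == (cond == "wet")])
    se <- params$noise_sd_c * sqrt(rowSums((B %*% solve(crossprod(X))) * B))
    expect_true(all(abs(fitted_mid - truth_mid) < 4 * se))
    expect_lt(mean(abs(fitted_mid - truth_mid)), 0.2)
  }
})

test_that("1000 simulated years reproduce the training statistics", {
  m <- test_model()
  train <- daily_monthly_stats(test_obs(), real_months = TRUE)
  sim <- simulate_daily(m, 1000, seed = 2024)
  got <- daily_monthly_stats(sim)
  expect_lt(max(abs(got$wet_frac - train$wet_frac)), 0.02)
  expect_lt(max(abs(got$amount_mean / train$amount_mean - 1)), 0.05)
  expect_lt(max(abs(got$temp_mean - train$temp_mean)), 0.3)
})

test_that("known-truth recovery stays within Monte-Carlo bounds", {
  # end-to-end: synthetic truth -> 20y fixture -> fit -> 1000y simulation.
  # The dominant error is the fixture's own sampling noise, so bounds are
  # 3 sigma of the 20-year monthly estimates.
  params <- synth_weather_params()
  truth <- synth_monthly_truth(params)
  m <- test_model()
  sim <- simulate_daily(m, 1000, seed = 77)
  got <- daily_monthly_stats(sim)
  days_m <- make_calendar(12)$days * 20
  se_wet <- sqrt(truth$wet_prob * (1 - truth$wet_prob) / days_m)
  expect_true(all(abs(got$wet_frac - truth$wet_prob) < 3 * se_wet + 0.005))
  n_wet <- days_m * truth$wet_prob
  se_amt <- sqrt(params$gamma_shape) * params$gamma_scale / sqrt(n_wet)
  expect_true(all(abs(got$amount_mean - truth$amount_mean) <
                    3 * se_amt + 0.05 * truth$amount_mean))
  expect_true(all(abs(got$temp_mean - truth$temp_mean) < 0.3))
})

test_that("fitting is invariant to the start year of the observations", {
  obs <- test_obs()
  shifted <- daily_series("2005-01-01", obs$precip_mm, obs$tmin_c, obs$tmax_c)
  m1 <- fit_weathergen(obs)        # starts 2001, same leap-year phase
  m2 <- fit_weathergen(shifted)
  m1$n_days_fit <- m2$n_days_fit   # equal anyway
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("model serialization round-trips through the text format", {
  m <- test_model()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_weathergen(m, f)
  m2 <- read_weathergen(f)
  a <- simulate_daily(m, 3, seed = 55)
  b <- simulate_daily(m2, 3, seed = 55)
  expect_equal(a$precip_mm, b$precip_mm, tolerance = 1e-9)
  expect_equal(a$tmin_c, b$tmin_c, tolerance = 1e-9)
  expect_equal(a$tmax_c, b$tmax_c, tolerance = 1e-9)
})

test_that("seasonal profiles and their comparison metrics behave", {
  one <- subannual_series(matrix(1:12, 1), "temp_mean_c")
  expect_equal(seasonal_profile(one)$values, as.numeric(1:12))
  two <- subannual_series(rbind(c(4, rep(0, 11)), c(6, rep(0, 11))),
                          "temp_mean_c")
  expect_equal(seasonal_profile(two)$values[1], 5)

  pa <- structure(list(N = 2L, values = c(0, 2), kind = "temp_mean_c"),
                  class = "interval_climatology")
  pb <- structure(list(N = 2L, values = c(1, 1), kind = "temp_mean_c"),
                  class = "interval_climatology")
  expect_equal(profile_mae(pa, pa), 0)
  expect_equal(profile_mae(pa, pb), 1)
  pc <- structure(list(N = 2L, values = c(1, 3), kind = "temp_mean_c"),
                  class = "interval_climatology")
  expect_equal(profile_mae(pa, pc), 1)

  p100 <- structure(list(N = 2L, values = c(100, 100), kind = "x"),
                    class = "interval_climatology")
  p102 <- structure(list(N = 2L, values = c(102.9, 102.9), kind = "x"),
                    class = "interval_climatology")
  expect_equal(normalised_bias(p100, p100), 0)
  expect_equal(normalised_bias(p100, p102), 2.9)
  p10 <- structure(list(N = 1L, values = 10, kind = "x"),
                   class = "interval_climatology")
  p9 <- structure(list(N = 1L, values = 9, kind = "x"),
                  class = "interval_climatology")
  expect_equal(normalised_bias(p10, p9), -10)
  pz <- structure(list(N = 1L, values = 0, kind = "x"),
                  class = "interval_climatology")
  expect_error(normalised_bias(pz, p9), "undefined")
  expect_error(profile_mae(p10, pa), "interval counts")
})
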