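# Synthetic fixtures with analytically known statistics: daily weather,
# Holocene anomaly grids and projection scaler tables. These stand in for
# station observations, the gridded pollen-based anomaly product and
# GCM-derived delta tables so the whole pipeline runs and is testable
# with no external data. They are testing fixtures, not climate
# emulators.

#' Parameters of the synthetic daily-weather fixture
#'
#' A sinusoidal seasonal temperature cycle plus iid normal noise, iid
#' per-month Bernoulli wet-day occurrence, and gamma wet-day amounts.
#' Every monthly statistic (wet-day probability, mean wet-day amount
#' `shape * scale`, mean temperature) is analytic, so generator fits can
#' be checked against known truth. Defaults emulate a wet oceanic
#' Scottish Highlands climate (annual mean 8.5 degrees C, about 1150 mm
#' of precipitation per year, winter-wet seasonality).
#'
#' @param mean_temp_c Annual mean temperature (degrees C).
#' @param seasonal_amp_c Amplitude of the seasonal cycle (degrees C);
#'   the daily mean is `mean - amp * cos(2*pi*(d - 15)/365)` (coldest in
#'   mid-January).
#' @param wet_prob Per-month wet-day probability (12 values in [0, 1]).
#' @param gamma_shape,gamma_scale Per-month gamma parameters of wet-day
#'   amounts (scalars are recycled); mean amount is `shape * scale` mm.
#' @param diurnal_range_c Constant tmax - tmin spread (> 0).
#' @param noise_sd_c SD of the daily temperature noise (> 0).
#' @return An object of class `synth_weather_params`.
#' @export
synth_weather_params <- function(
    mean_temp_c = 8.5, seasonal_amp_c = 5.5,
    wet_prob = c(0.60, 0.58, 0.55, 0.50, 0.46, 0.44,
                 0.45, 0.48, 0.52, 0.57, 0.60, 0.62),
    gamma_shape = 0.9,
    gamma_scale = c(8.0, 7.5, 6.8, 6.0, 5.5, 5.2,
                    5.3, 5.8, 6.4, 7.2, 7.8, 8.2),
    diurnal_range_c = 6, noise_sd_c = 1.5) {
  wet_prob <- rep_len(as.numeric(wet_prob), 12L)
  gamma_shape <- rep_len(as.numeric(gamma_shape), 12L)
  gamma_scale <- rep_len(as.numeric(gamma_scale), 12L)
  if (any(wet_prob < 0 | wet_prob > 1))
    stop("wet_prob must be in [0, 1]", call. = FALSE)
  if (any(gamma_shape <= 0) || any(gamma_scale <= 0))
    stop("gamma parameters must be > 0", call. = FALSE)
  if (diurnal_range_c <= 0 || noise_sd_c < 0)
    stop("diurnal_range_c must be > 0 and noise_sd_c >= 0", call. = FALSE)
  structure(
    list(mean_temp_c = mean_temp_c, seasonal_amp_c = seasonal_amp_c,
         wet_prob = wet_prob, gamma_shape = gamma_shape,
         gamma_scale = gamma_scale, diurnal_range_c = diurnal_range_c,
         noise_sd_c = noise_sd_c),
    class = "synth_weather_params")
}

# daily mean temperature curve of the fixture on the 365-day year
synth_temp_curve <- function(params, d = 1:365) {
  params$mean_temp_c -
    params$seasonal_amp_c * cos(2 * pi * (d - 15) / 365)
}

#' True monthly statistics of the synthetic fixture
#'
#' The analytic per-month wet-day probability, mean wet-day amount and
#' mean daily temperature implied by a [synth_weather_params()], for use
#' as ground truth in generator-recovery checks.
#'
#' @param params A [synth_weather_params()].
#' @return List with numeric vectors `wet_prob`, `amount_mean_mm`,
#'   `temp_mean_c` (length 12 each).
#' @export
synth_monthly_truth <- function(params) {
  stopifnot(inherits(params, "synth_weather_params"))
  cal <- make_calendar(12)
  curve <- synth_temp_curve(params)
  list(wet_prob = params$wet_prob,
       amount_mean_mm = params$gamma_shape * params$gamma_scale,
       temp_mean_c = as.numeric(tapply(curve, cal$interval_of_day, mean)))
}

#' Generate a synthetic daily observation series
#'
#' Draws `365 * n_years` days of fixture weather on the real calendar
#' (starting 2001-01-01; leap days take the Feb 28 value of the seasonal
#' curve, mirroring how station records are folded when fitting):
#' per-month Bernoulli wet days with gamma amounts, and temperatures
#' `tmid = curve(d) + noise` split symmetrically into
#' `tmin = tmid - range/2`, `tmax = tmid + range/2` (the min/max
#' invariant holds by construction). Seed-reproducible.
#'
#' @param params A [synth_weather_params()].
#' @param n_years Number of years (>= 1).
#' @param seed Integer RNG seed.
#' @return A [daily_series()].
#' @export
make_synthetic_obs <- function(params, n_years, seed = 1L) {
  stopifnot(inherits(params, "synth_weather_params"), n_years >= 1L)
  set.seed(seed, kind = "Mersenne-Twister")
  n <- n_years * 365L
  dates <- as.Date("2001-01-01") + seq_len(n) - 1L
  month <- as.integer(format(dates, "%m"))
  wet <- stats::runif(n) < params$wet_prob[month]
  precip <- numeric(n)
  widx <- which(wet)
  if (length(widx))
    precip[widx] <- stats::rgamma(length(widx),
                                  shape = params$gamma_shape[month[widx]],
                                  scale = params$gamma_scale[month[widx]])
  # keep wet amounts above the default trace threshold so the fixture's
  # wet flags coincide with the generator's
  precip[widx] <- pmax(precip[widx], 0.11)
  tmid <- synth_temp_curve(params, doy365(dates)) +
    stats::rnorm(n, sd = params$noise_sd_c)
  half <- params$diurnal_range_c / 2
  daily_series(as.Date("2001-01-01"), precip, tmid - half, tmid + half)
}

#' Generate a synthetic Holocene anomaly series
#'
#' Builds an [anomaly_series()] from explicit 13-knot profiles or from
#' the canned `"holocene_like"` preset, which reproduces the qualitative
#' shape of northern-European pollen-based reconstructions: a cold
#' (about -4 degrees C) and dry (about -0.9 mm/day at 10 ka BP) early
#' Holocene, a mid-Holocene wet period peaking near 3-4 ka BP, and
#' near-zero anomalies at 0 BP.
#'
#' @param profile `"zero"`, `"holocene_like"`, or a list with numeric
#'   vectors `dT_c` and `dP_mm_day` (13 values each, ages 0..12000 BP).
#' @param cell Length-2 `(lon_floor, lat_floor)` of the grid cell.
#' @return An [anomaly_series()].
#' @export
make_synthetic_anomaly <- function(profile = "holocene_like",
                                   cell = c(-5, 58)) {
  if (is.character(profile)) {
    profile <- match.arg(profile, c("zero", "holocene_like"))
    profile <- switch(profile,
      zero = list(dT_c = rep(0, 13), dP_mm_day = rep(0, 13)),
      holocene_like = list(
        # ages 0, 1000, ..., 12000 BP
        dT_c = c(0, 0.1, 0.2, 0.2, 0.1, 0, -0.1, -0.2, -0.3,
                 -1.3, -2.3, -3.3, -4.3),
        dP_mm_day = c(0, 0.10, 0.35, 0.45, 0.48, 0.45, 0.40, 0.35, 0.10,
                      -0.50, -0.90, -0.70, -0.50)))
  }
  if (length(profile$dT_c) != 13L || length(profile$dP_mm_day) != 13L)
    stop("profile must supply 13 (dT, dP) knot pairs", call. = FALSE)
  anomaly_series(cell, profile$dT_c, profile$dP_mm_day)
}

#' Generate synthetic projection scaler sets
#'
#' Per-period scaler sets ramping linearly from zero to a given end
#' state across `n_periods` overlapping-decade labels (2021-2040,
#' 2031-2050, ..., 2081-2100 for the default 7), emulating
#' delta-change tables derived from GCM projections.
#'
#' @param dT_final Per-interval additive temperature delta reached in the
#'   last period (degrees C); scalars are recycled to `N`.
#' @param dP_rel_final Per-interval relative precipitation delta reached
#'   in the last period.
#' @param n_periods Number of periods (default 7).
#' @param N Intervals per year (default 12).
#' @return List of [scaler_set()] ordered by period.
#' @export
make_synthetic_scalers <- function(dT_final, dP_rel_final = 0,
                                   n_periods = 7L, N = 12L) {
  stopifnot(n_periods >= 1L)
  dT_final <- rep_len(as.numeric(dT_final), N)
  dP_rel_final <- rep_len(as.numeric(dP_rel_final), N)
  lapply(seq_len(n_periods), function(i) {
    frac <- i / n_periods
    scaler_set(period = c(2021 + 10 * (i - 1), 2040 + 10 * (i - 1)),
               dT = dT_final * frac, dP_rel = dP_rel_final * frac)
  })
}
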