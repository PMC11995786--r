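# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# 20-year synthetic observation record with default (Scottish-oceanic)
# parameters, plus its fitted generator model
test_obs <- function() {
  if (is.null(.fixtures$obs))
    .fixtures$obs <- make_synthetic_obs(synth_weather_params(), 20, seed = 42)
  .fixtures$obs
}

test_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- fit_weathergen(test_obs())
  .fixtures$model
}

# monthly statistics of a daily series (wet fraction, mean wet amount,
# mean temperature), computed directly and independently of the fit.
# Observation records carry real calendar dates (with leap days), so
# their days are grouped by real month; simulated series live on the
# abstract 365-day year and are grouped by the nominal calendar.
daily_monthly_stats <- function(series, wet_threshold = 0.1,
                                real_months = FALSE) {
  cal <- make_calendar(12)
  mon <- if (real_months) {
    as.integer(format(series$start_date + seq_len(length(series)) - 1, "%m"))
  } else {
    rep_len(cal$interval_of_day, length(series))
  }
  wet <- series$precip_mm > wet_threshold
  tmean <- (series$tmin_c + series$tmax_c) / 2
  list(
    wet_frac = as.numeric(tapply(wet, mon, mean)),
    amount_mean = as.numeric(tapply(series$precip_mm[wet], mon[wet], mean)),
    temp_mean = as.numeric(tapply(tmean, mon, mean)))
}

# two-cell anomaly grid covering the Altnaharra/Cassley cell (-5, 58)
# and the Wick cell (-4, 58)
test_anomaly_grid <- function(profile = "holocene_like") {
  list(
    "-5,58" = make_synthetic_anomaly(profile, cell = c(-5, 58)),
    "-4,58" = make_synthetic_anomaly(profile, cell = c(-4, 58)))
}

alt_site <- function() site_meta("Altnaharra", 58.288, -4.442, 81)
css_site <- function() site_meta("Cassley", 58.168, -4.727, 99)
wck_site <- function() site_meta("Wick", 58.454, -3.09, 36)
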