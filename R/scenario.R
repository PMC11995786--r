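# Delta-change scenario modulation: per-interval scalers between a
# baseline and a future climatology, temporally interpolated across
# projection periods and applied to the final decades of the baseline.

#' Per-interval climatology of a sub-annual series
#'
#' Averages each sub-annual interval over all years:
#' \eqn{\bar X_n = (1/Y) \sum_y X_{n,y}} — e.g. all January values of a
#' monthly series are averaged into a single January mean.
#'
#' @param series A [subannual_series()].
#' @return An object of class `interval_climatology` (fields `N`,
#'   `values`, `kind`).
#' @export
interval_climatology <- function(series) {
  stopifnot(inherits(series, "subannual_series"))
  structure(list(N = series$N, values = colMeans(series$values),
                 kind = series$kind),
            class = "interval_climatology")
}

#' Seasonal profile of a sub-annual series
#'
#' Diagnostic alias for [interval_climatology()]: the mean seasonal cycle
#' of a simulated or observed series, used to compare a generator's
#' output against its training data.
#'
#' @inheritParams interval_climatology
#' @return An `interval_climatology`.
#' @export
seasonal_profile <- function(series) interval_climatology(series)

#' Mean absolute error between two seasonal profiles
#'
#' @param obs_profile,sim_profile `interval_climatology` objects with the
#'   same number of intervals.
#' @return Mean over intervals of `|obs - sim|`, in the profile's units.
#' @export
profile_mae <- function(obs_profile, sim_profile) {
  if (obs_profile$N != sim_profile$N)
    stop("profiles have different interval counts: ", obs_profile$N,
         " vs ", sim_profile$N, call. = FALSE)
  mean(abs(obs_profile$values - sim_profile$values))
}

#' Normalised seasonal bias between two profiles
#'
#' @inheritParams profile_mae
#' @return `100 * (mean(sim) - mean(obs)) / mean(obs)`, a percentage.
#' @export
normalised_bias <- function(obs_profile, sim_profile) {
  if (obs_profile$N != sim_profile$N)
    stop("profiles have different interval counts: ", obs_profile$N,
         " vs ", sim_profile$N, call. = FALSE)
  mo <- mean(obs_profile$values)
  if (mo == 0)
    stop("normalised bias is undefined: observed profile mean is zero",
         call. = FALSE)
  100 * (mean(sim_profile$values) - mo) / mo
}

#' Delta-change scaler set for one projection period
#'
#' Per-interval deltas between a future and the baseline climatology:
#' additive for temperature, relative (dimensionless) for precipitation.
#'
#' @param period Length-2 numeric, `(start_year, end_year)` CE.
#' @param dT Additive temperature deltas, one per interval (degrees C).
#' @param dP_rel Relative precipitation deltas, one per interval; must
#'   exceed -1 so modulated precipitation stays non-negative.
#' @return An object of class `scaler_set`.
#' @export
scaler_set <- function(period, dT, dP_rel) {
  if (length(period) != 2L || period[2L] < period[1L])
    stop("`period` must be (start_year, end_year) with start <= end",
         call. = FALSE)
  if (length(dT) != length(dP_rel))
    stop("dT and dP_rel must have the same length", call. = FALSE)
  if (any(dP_rel <= -1))
    stop("dP_rel must be > -1 in every interval", call. = FALSE)
  structure(list(period = as.numeric(period), dT = as.numeric(dT),
                 dP_rel = as.numeric(dP_rel)),
            class = "scaler_set")
}

#' Temperature scalers between baseline and future climatologies
#'
#' Signed per-interval difference
#' \eqn{\Delta T_n = \bar T_{n,future} - \bar T_{n,base}}.
#'
#' @param base,future `interval_climatology` objects with equal N.
#' @return Numeric vector of N additive deltas (degrees C).
#' @export
temp_scalers <- function(base, future) {
  if (base$N != future$N)
    stop("climatologies have different interval counts", call. = FALSE)
  future$values - base$values
}

#' Precipitation scalers between baseline and future climatologies
#'
#' Relative per-interval difference
#' \eqn{\Delta P_n = (\bar P_{n,future} - \bar P_{n,base}) / \bar P_{n,base}}.
#'
#' @inheritParams temp_scalers
#' @return Numeric vector of N dimensionless relative deltas.
#' @export
precip_scalers <- function(base, future) {
  if (base$N != future$N)
    stop("climatologies have different interval counts", call. = FALSE)
  bad <- which(base$values <= 0)
  if (length(bad))
    stop("baseline precipitation mean is <= 0 in interval ", bad[1L],
         "; relative scaler undefined", call. = FALSE)
  (future$values - base$values) / base$values
}

#' Interpolate scaler sets into a per-year trajectory
#'
#' For each sub-annual interval independently, an interpolating cubic
#' spline is fitted through the period scaler knots — anchored at zero at
#' projection year 0 (the unmodulated baseline, year 2000 CE) with each
#' period contributing a knot at its midpoint year — and evaluated at
#' every projection year 1..`horizon_years`. Knot values are reproduced
#' exactly; beyond the last anchor the trajectory is held constant. Each
#' interval's trajectory depends only on that interval's knots, so the
#' projected change in seasonality is preserved. Spline overshoot that
#' would drive a relative precipitation delta to -1 or below is clipped
#' to -0.999 with a warning.
#'
#' @param sets List of [scaler_set()] (non-overlapping, any order).
#' @param horizon_years Projection horizon (default 100).
#' @param year0 Calendar year mapped to projection year 0 (default 2000).
#' @return An object of class `scaler_trajectory` with matrices `dT` and
#'   `dP_rel` of shape `horizon_years x N`, plus the knot table and an
#'   evaluator `at(years)` used for exact knot checks.
#' @export
interpolate_scalers <- function(sets, horizon_years = 100L, year0 = 2000) {
  stopifnot(length(sets) >= 1L)
  starts <- vapply(sets, function(s) s$period[1L], numeric(1))
  sets <- sets[order(starts)]
  # periods may overlap (decade-stepped 20-year windows are the norm) but
  # their midpoints must be distinct and increasing: they are spline knots
  mids <- vapply(sets, function(s) mean(s$period), numeric(1))
  if (any(diff(mids) <= 0))
    stop("scaler period midpoints must be strictly increasing", call. = FALSE)
  N <- length(sets[[1L]]$dT)
  if (any(vapply(sets, function(s) length(s$dT), integer(1)) != N))
    stop("scaler sets have inconsistent interval counts", call. = FALSE)
  anchors <- c(0, vapply(sets, function(s) mean(s$period), numeric(1)) - year0)
  if (any(anchors[-1L] <= 0))
    stop("all period midpoints must lie after year0 = ", year0, call. = FALSE)
  kT <- rbind(0, do.call(rbind, lapply(sets, function(s) s$dT)))
  kP <- rbind(0, do.call(rbind, lapply(sets, function(s) s$dP_rel)))

  eval_at <- function(years) {
    dT <- vapply(seq_len(N), function(n) interp_knots(anchors, kT[, n], years),
                 numeric(length(years)))
    dP <- vapply(seq_len(N), function(n) interp_knots(anchors, kP[, n], years),
                 numeric(length(years)))
    dT <- matrix(dT, nrow = length(years))
    dP <- matrix(dP, nrow = length(years))
    nclip <- sum(dP <= -1)
    if (nclip > 0L) {
      warning(nclip, " interpolated dP_rel value(s) <= -1 clipped to -0.999",
              call. = FALSE)
      dP[dP <= -1] <- -0.999
    }
    list(dT = dT, dP_rel = dP)
  }
  tr <- eval_at(seq_len(horizon_years))
  structure(
    list(horizon_years = as.integer(horizon_years), N = N,
         dT = tr$dT, dP_rel = tr$dP_rel,
         anchors = anchors, knots_dT = kT, knots_dP = kP, at = eval_at),
    class = "scaler_trajectory")
}

#' Apply a scaler trajectory to the baseline tail
#'
#' Elementwise modulation of the final `horizon_years` of the baseline:
#' temperature is shifted additively
#' (`temp + dT`), precipitation multiplicatively (`precip * (1 + dP_rel)`).
#'
#' @param precip_tail,temp_tail [subannual_series()] with exactly
#'   `traj$horizon_years` years and `traj$N` intervals.
#' @param traj A [interpolate_scalers()] trajectory.
#' @return List with modulated `precip` and `temp` series.
#' @export
apply_scenario <- function(precip_tail, temp_tail, traj) {
  stopifnot(inherits(traj, "scaler_trajectory"))
  check_same_shape(precip_tail, temp_tail, "precip/temp tails")
  if (precip_tail$Y != traj$horizon_years || precip_tail$N != traj$N)
    stop("tail shape ", precip_tail$Y, "x", precip_tail$N,
         " does not match trajectory ", traj$horizon_years, "x", traj$N,
         call. = FALSE)
  list(
    precip = subannual_series(precip_tail$values * (1 + traj$dP_rel),
                              kind = "precip_total_mm",
                              epoch = precip_tail$epoch),
    temp = subannual_series(temp_tail$values + traj$dT,
                            kind = "temp_mean_c", epoch = temp_tail$epoch))
}
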