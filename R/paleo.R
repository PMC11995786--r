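# Holocene paleoclimate modulation: grid-cell anomaly lookup, spline
# downscaling from 1000-year knots to yearly resolution, and piecewise
# addition onto the historical baseline.

#' Holocene anomaly series for one grid cell
#'
#' Temperature and precipitation anomalies relative to the present-day
#' (0 BP = 2000 CE) reference, at 13 knots spaced 1000 years apart over
#' the last 12,000 years, for one 1-degree grid cell.
#'
#' @param cell Length-2 numeric `(lon_floor, lat_floor)`: the lower-left
#'   corner of the 1-degree cell.
#' @param dT_c Temperature anomaly (degrees C) at ages 0, 1000, ...,
#'   12000 BP (13 values, ordered by increasing age).
#' @param dP_mm_day Daily precipitation anomaly (mm/day) at the same knots.
#' @return An object of class `anomaly_series`.
#' @export
anomaly_series <- function(cell, dT_c, dP_mm_day) {
  if (length(cell) != 2L)
    stop("`cell` must be (lon_floor, lat_floor)", call. = FALSE)
  if (length(dT_c) != 13L || length(dP_mm_day) != 13L)
    stop("anomaly series needs exactly 13 knots (0..12000 BP by 1000), got ",
         length(dT_c), call. = FALSE)
  structure(
    list(cell = as.numeric(cell), ages_bp = seq(0L, 12000L, by = 1000L),
         dT_c = as.numeric(dT_c), dP_mm_day = as.numeric(dP_mm_day)),
    class = "anomaly_series")
}

#' @export
print.anomaly_series <- function(x, ...) {
  cat(sprintf("<anomaly_series> cell (%g, %g): dT %.2f..%.2f C, dP %.2f..%.2f mm/day\n",
              x$cell[1L], x$cell[2L], min(x$dT_c), max(x$dT_c),
              min(x$dP_mm_day), max(x$dP_mm_day)))
  invisible(x)
}

#' Select the anomaly series covering a site
#'
#' Containing-cell lookup on the 1-degree grid: the site belongs to the
#' cell `[floor(lon), floor(lon)+1) x [floor(lat), floor(lat)+1)`
#' (half-open on the upper edges). Nearby sites in the same cell share
#' one anomaly series.
#'
#' @param site A [site_meta()].
#' @param grid Named list of [anomaly_series()] as returned by
#'   [read_anomaly_grid()].
#' @return The covering [anomaly_series()].
#' @export
select_grid_cell <- function(site, grid) {
  stopifnot(inherits(site, "site_meta"))
  want <- c(floor(site$lon), floor(site$lat))
  for (a in grid) {
    if (identical(a$cell, want)) return(a)
  }
  stop(sprintf("no anomaly grid cell covers site %s (%.3f N, %.3f E): need cell (%g, %g)",
               site$name, site$lat, site$lon, want[1L], want[2L]),
       call. = FALSE)
}

#' Downscale a 1000-year anomaly series to yearly resolution
#'
#' Fits an interpolating cubic spline (natural, zero smoothing) through
#' the 13 (age, anomaly) knots and evaluates it at every series year.
#' Ages map to series years via `year = 12000 - age_bp` (0 BP = 2000 CE
#' = year 12,000; the series starts at year 1 = 11,999 BP). Knot years
#' reproduce the knot anomalies exactly. The anomaly is annual: every
#' interval within a year carries the same value.
#'
#' @param anomaly An [anomaly_series()].
#' @param n_years Number of historical years (default 12000).
#' @return An object of class `dense_anomaly`: per-year vectors `dT_c`
#'   and `dP_mm_day` of length `n_years`.
#' @export
downscale_anomaly <- function(anomaly, n_years = 12000L) {
  stopifnot(inherits(anomaly, "anomaly_series"))
  knot_years <- 12000 - anomaly$ages_bp
  years <- seq_len(n_years)
  structure(
    list(n_years = as.integer(n_years),
         dT_c = interp_knots(knot_years, anomaly$dT_c, years),
         dP_mm_day = interp_knots(knot_years, anomaly$dP_mm_day, years)),
    class = "dense_anomaly")
}

#' Apply the Holocene anomaly to the historical baseline
#'
#' Piecewise addition of the downscaled anomaly onto the baseline
#' sub-annual series. Temperature: `temp + dT`. Precipitation: the daily
#' anomaly is converted to an interval total by the interval's day count
#' (`dP_mm_day * D_n`), added, and floored at zero; the number of floored
#' cells is reported via a message.
#'
#' @param precip,temp [subannual_series()] covering the historical years.
#' @param dense A [downscale_anomaly()] result with matching year count.
#' @param calendar The [make_calendar()] calendar of the series.
#' @return List with modulated `precip` and `temp` series and the count
#'   of floored precipitation cells (`n_floored`).
#' @export
apply_paleo <- function(precip, temp, dense, calendar) {
  stopifnot(inherits(dense, "dense_anomaly"),
            inherits(calendar, "interval_calendar"))
  check_same_shape(precip, temp, "precip/temp")
  if (precip$Y != dense$n_years)
    stop("series has ", precip$Y, " years but dense anomaly has ",
         dense$n_years, call. = FALSE)
  if (precip$N != calendar$N)
    stop("series N = ", precip$N, " does not match calendar N = ",
         calendar$N, call. = FALSE)
  dP_interval <- outer(dense$dP_mm_day, as.numeric(calendar$days))
  p_new <- precip$values + dP_interval
  n_floored <- sum(p_new < 0)
  if (n_floored > 0L) {
    message(n_floored,
            " precipitation cell(s) floored at 0 during paleo modulation")
    p_new[p_new < 0] <- 0
  }
  list(
    precip = subannual_series(p_new, kind = "precip_total_mm",
                              epoch = precip$epoch),
    temp = subannual_series(temp$values + dense$dT_c, kind = "temp_mean_c",
                            epoch = temp$epoch),
    n_floored = n_floored)
}
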