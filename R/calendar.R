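#' Sub-annual interval calendar
#'
#' Partitions a 365-day model year into N intervals and records, for each
#' interval, its day count \eqn{D_n} and the Julian date \eqn{J_n} of its
#' middle day. The day counts scale the 30-day reference interval of the
#' unscaled Thornthwaite PET; the median Julian dates feed the solar
#' declination used for day length.
#'
#' `N = 12` gives calendar months on a 365-day (no leap) year; `N = 52`
#' gives fifty-one 7-day weeks plus a final 8-day week so that the day
#' counts sum to exactly 365 and precipitation mass is conserved. For
#' even-length intervals the lower middle day is taken as \eqn{J_n}.
#'
#' @param N Intervals per year: 12 (monthly) or 52 (weekly).
#' @return An object of class `interval_calendar` with fields `N`,
#'   `days` (\eqn{D_n}), `julian_mid` (\eqn{J_n}), `interval_of_day`
#'   (length-365 map from day of year to interval index).
#' @examples
#' cal <- make_calendar(12)
#' sum(cal$days)        # 365
#' cal$julian_mid[1]    # 16, the middle of Jan 1-31
#' @export
make_calendar <- function(N) {
  if (!length(N) == 1L || !N %in% c(12, 52))
    stop("unsupported interval count N = ", N, "; must be 12 or 52",
         call. = FALSE)
  N <- as.integer(N)
  days <- if (N == 12L) {
    c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  } else {
    c(rep(7L, 51L), 8L)
  }
  stopifnot(sum(days) == 365L)
  last <- cumsum(days)
  first <- last - days + 1L
  julian_mid <- first + (days - 1L) %/% 2L   # lower middle for even lengths
  structure(
    list(N = N, days = days, julian_mid = julian_mid,
         interval_of_day = rep.int(seq_len(N), days)),
    class = "interval_calendar")
}

#' @export
print.interval_calendar <- function(x, ...) {
  cat(sprintf("<interval_calendar> N = %d (%s)\n", x$N,
              if (x$N == 12L) "monthly" else "weekly"))
  invisible(x)
}

#' Daily mean temperature from the min/max pair
#'
#' The mean of the daily minimum and maximum is used as the approximation
#' of the mean daily temperature throughout the pipeline.
#'
#' @param tmin_c,tmax_c Daily minimum / maximum temperature (degrees C);
#'   vectors of equal length.
#' @return `(tmin_c + tmax_c) / 2`.
#' @export
daily_mean_temp <- function(tmin_c, tmax_c) {
  bad <- which(tmin_c > tmax_c)
  if (length(bad))
    stop("tmin_c > tmax_c at position ", bad[1L], call. = FALSE)
  (tmin_c + tmax_c) / 2
}

#' Aggregate a daily series to sub-annual intervals
#'
#' Precipitation is summed within each interval; temperature (the daily
#' min/max mean) is averaged. The daily series must contain a whole number
#' of 365-day years aligned to the calendar (the weather generator emits
#' exactly such series). Annual precipitation totals are preserved exactly.
#'
#' @param daily A [daily_series()].
#' @param calendar An [make_calendar()] calendar.
#' @param epoch Calendar year assigned to the first year of the output.
#' @return A list with components `precip` and `temp`, both
#'   [subannual_series()] objects of shape `years x N`.
#' @export
aggregate_daily <- function(daily, calendar, epoch = 1L) {
  stopifnot(inherits(daily, "daily_series"),
            inherits(calendar, "interval_calendar"))
  n <- length(daily)
  if (n %% 365L != 0L)
    stop("daily series length ", n,
         " is not a whole number of 365-day years (partial trailing year)",
         call. = FALSE)
  Y <- n %/% 365L
  grp <- calendar$interval_of_day
  # days x years matrices; rowsum over interval groups gives N x years
  pm <- matrix(daily$precip_mm, nrow = 365L)
  tm <- matrix((daily$tmin_c + daily$tmax_c) / 2, nrow = 365L)
  psum <- rowsum(pm, grp, reorder = TRUE)
  tmean <- rowsum(tm, grp, reorder = TRUE) / calendar$days
  list(
    precip = subannual_series(t(psum), kind = "precip_total_mm", epoch = epoch),
    temp   = subannual_series(t(tmean), kind = "temp_mean_c",    epoch = epoch))
}
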