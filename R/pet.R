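# Potential evapotranspiration by the Thornthwaite method, generalised
# from calendar months to arbitrary sub-annual intervals and scaled by
# day length and interval day count.

#' Annual heat index
#'
#' \eqn{I = \sum_n (\max(t_n, 0)/5)^{1.514} \cdot (12/N)}: each
#' interval's heat index is computed as if it were a month and the sum is
#' rescaled by `12/N` so the annual index does not depend on the interval
#' count. Sub-zero temperatures contribute nothing (standard Thornthwaite
#' practice).
#'
#' @param temps One year of interval mean temperatures (length N,
#'   degrees C).
#' @param N Intervals per year (defaults to `length(temps)`).
#' @return The dimensionless annual heat index.
#' @export
heat_index <- function(temps, N = length(temps)) {
  if (length(temps) != N)
    stop("expected ", N, " interval temperatures, got ", length(temps),
         call. = FALSE)
  sum((pmax(temps, 0) / 5)^1.514) * (12 / N)
}

#' Thornthwaite exponent
#'
#' The empirical cubic in the annual heat index:
#' \eqn{a = 675\times10^{-9} I^3 - 771\times10^{-7} I^2
#'      + 1792\times10^{-5} I + 0.49239}.
#'
#' @param I Annual heat index (>= 0).
#' @return The exponent `a`.
#' @export
exponent_a <- function(I) {
  stopifnot(all(I >= 0))
  675e-9 * I^3 - 771e-7 * I^2 + 1792e-5 * I + 0.49239
}

#' Unscaled interval PET
#'
#' \eqn{PET_n = 16 (10 t_n / I)^a} mm, valid for a reference 30-day
#' interval with 12 hours of daylight; zero when `t_n <= 0`.
#'
#' @param t_n Interval mean temperature (degrees C); vectorised.
#' @param I Annual heat index.
#' @param a Thornthwaite exponent (defaults to [exponent_a()] of `I`).
#' @return PET in mm per reference interval.
#' @export
pet_unscaled <- function(t_n, I, a = exponent_a(I)) {
  if (I == 0 && any(t_n > 0))
    stop("heat index 0 is inconsistent with a positive interval temperature",
         call. = FALSE)
  ifelse(t_n <= 0, 0, 16 * (10 * pmax(t_n, 0) / max(I, .Machine$double.eps))^a)
}

#' Solar declination
#'
#' Degree-form approximation
#' \eqn{\delta_n = 23.45 \sin((J_n - 81) \cdot 360/365)} with the
#' argument in degrees.
#'
#' @param J_n Median Julian date of the interval (1..365); vectorised.
#' @return Declination in degrees.
#' @export
solar_declination <- function(J_n) {
  stopifnot(all(J_n >= 1), all(J_n <= 365))
  23.45 * sin((J_n - 81) * (360 / 365) * pi / 180)
}

#' Day length
#'
#' \eqn{L_n = (24/\pi)\arccos(-\tan(lat)\tan(\delta_n))} hours. The
#' arccos argument is clamped to [-1, 1], so polar day returns 24 h and
#' polar night 0 h instead of a domain error.
#'
#' @param lat Latitude in degrees; scalar.
#' @param delta Solar declination in degrees; vectorised.
#' @return Day length in hours.
#' @export
day_length <- function(lat, delta) {
  x <- -tan(lat * pi / 180) * tan(delta * pi / 180)
  (24 / pi) * acos(pmin(pmax(x, -1), 1))
}

#' Scale PET by day length and interval length
#'
#' \eqn{PET'_n = PET_n \cdot (L_n/12) \cdot (D_n/30)}: corrects the
#' reference 30-day, 12-hour-daylight assumption of [pet_unscaled()].
#'
#' @param PET_n Unscaled PET (mm); vectorised.
#' @param L_n Day length (hours, 0..24).
#' @param D_n Interval day count (>= 1).
#' @return Scaled PET in mm per interval.
#' @export
scale_pet <- function(PET_n, L_n, D_n) {
  stopifnot(all(PET_n >= 0), all(L_n >= 0), all(L_n <= 24), all(D_n >= 1))
  PET_n * (L_n / 12) * (D_n / 30)
}

#' PET series from a temperature series
#'
#' For every year of the input: the annual heat index from that year's
#' interval temperatures, the exponent, the unscaled interval PET, and
#' the day-length / day-count scaling from the site latitude and the
#' calendar's median Julian dates. The result is aligned with the input.
#'
#' @param temp A [subannual_series()] of kind `temp_mean_c`.
#' @param site A [site_meta()] (provides the latitude).
#' @param calendar The [make_calendar()] calendar of the series.
#' @return A [subannual_series()] of kind `pet_mm`.
#' @export
pet_series <- function(temp, site, calendar) {
  stopifnot(inherits(temp, "subannual_series"), inherits(site, "site_meta"),
            inherits(calendar, "interval_calendar"))
  if (temp$N != calendar$N)
    stop("series N = ", temp$N, " does not match calendar N = ", calendar$N,
         call. = FALSE)
  tv <- temp$values
  N <- temp$N
  I <- rowSums((pmax(tv, 0) / 5)^1.514) * (12 / N)
  a <- exponent_a(I)
  # 16 * (10 t / I)^a per cell, year-wise I and a; zero where t <= 0 or I = 0
  ratio <- 10 * pmax(tv, 0) / ifelse(I > 0, I, 1)
  pet0 <- 16 * ratio^a
  pet0[tv <= 0 | I == 0] <- 0
  L <- day_length(site$lat, solar_declination(calendar$julian_mid))
  scale <- (L / 12) * (calendar$days / 30)
  subannual_series(pet0 * rep(scale, each = temp$Y), kind = "pet_mm",
                   epoch = temp$epoch)
}

#' Net rainfall
#'
#' Elementwise `precipitation - PET`, the water-balance driver used by
#' peatland models; may be negative.
#'
#' @param precip A [subannual_series()] of kind `precip_total_mm`.
#' @param pet A [subannual_series()] of kind `pet_mm`, same shape.
#' @return A [subannual_series()] of kind `net_mm`.
#' @export
net_rainfall <- function(precip, pet) {
  check_same_shape(precip, pet, "precip/pet")
  subannual_series(precip$values - pet$values, kind = "net_mm",
                   epoch = precip$epoch)
}
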