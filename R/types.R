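#' Site metadata
#'
#' Describes an observation site: its name, coordinates and elevation.
#' The latitude is used by the day-length term of the potential
#' evapotranspiration calculation; the coordinates select the 1-degree
#' paleoclimate anomaly grid cell containing the site.
#'
#' @param name Site name (non-empty string).
#' @param lat Latitude in decimal degrees north, in [-90, 90].
#' @param lon Longitude in decimal degrees east, in [-180, 180].
#' @param elevation_m Elevation above sea level in metres (>= 0).
#'
#' @return An object of class `site_meta`.
#' @examples
#' site_meta("Altnaharra", lat = 58.288, lon = -4.442, elevation_m = 81)
#' @export
site_meta <- function(name, lat, lon, elevation_m = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (!is.numeric(lat) || length(lat) != 1L || is.na(lat) || lat < -90 || lat > 90)
    stop("`lat` must be a single value in [-90, 90]", call. = FALSE)
  if (!is.numeric(lon) || length(lon) != 1L || is.na(lon) || lon < -180 || lon > 180)
    stop("`lon` must be a single value in [-180, 180]", call. = FALSE)
  if (!is.numeric(elevation_m) || length(elevation_m) != 1L || is.na(elevation_m) ||
      elevation_m < 0)
    stop("`elevation_m` must be a single value >= 0", call. = FALSE)
  structure(
    list(name = name, lat = as.numeric(lat), lon = as.numeric(lon),
         elevation_m = as.numeric(elevation_m)),
    class = "site_meta")
}

#' @export
print.site_meta <- function(x, ...) {
  cat(sprintf("<site_meta> %s  (%.4f N, %.4f E, %.0f m)\n",
              x$name, x$lat, x$lon, x$elevation_m))
  invisible(x)
}

#' Daily weather series
#'
#' A continuous daily record of precipitation depth and minimum/maximum air
#' temperature, the training (and simulation) format of the weather
#' generator. The series must be gap-free and satisfy `tmin_c <= tmax_c` on
#' every day; precipitation must be non-negative.
#'
#' @param start_date First day of the record (`Date` or ISO-8601 string).
#' @param precip_mm Numeric vector of daily precipitation depths (mm).
#' @param tmin_c,tmax_c Numeric vectors of daily minimum / maximum
#'   temperature (degrees C), same length as `precip_mm`.
#'
#' @return An object of class `daily_series`.
#' @export
daily_series <- function(start_date, precip_mm, tmin_c, tmax_c) {
  start_date <- as.Date(start_date)
  if (length(start_date) != 1L || is.na(start_date))
    stop("`start_date` must be a single valid date", call. = FALSE)
  n <- length(precip_mm)
  if (length(tmin_c) != n || length(tmax_c) != n)
    stop("precip_mm, tmin_c and tmax_c must have equal length", call. = FALSE)
  if (n < 365L)
    stop("a daily series must span at least 365 days, got ", n, call. = FALSE)
  precip_mm <- as.numeric(precip_mm)
  tmin_c <- as.numeric(tmin_c)
  tmax_c <- as.numeric(tmax_c)
  if (anyNA(precip_mm) || anyNA(tmin_c) || anyNA(tmax_c))
    stop("daily series values must not contain missing values", call. = FALSE)
  bad <- which(precip_mm < 0)
  if (length(bad))
    stop("negative precipitation at row ", bad[1L], call. = FALSE)
  bad <- which(tmin_c > tmax_c)
  if (length(bad))
    stop("tmin_c > tmax_c at row ", bad[1L],
         sprintf(" (tmin=%.2f, tmax=%.2f)", tmin_c[bad[1L]], tmax_c[bad[1L]]),
         call. = FALSE)
  structure(
    list(start_date = start_date, precip_mm = precip_mm,
         tmin_c = tmin_c, tmax_c = tmax_c),
    class = "daily_series")
}

#' @export
length.daily_series <- function(x) length(x$precip_mm)

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d days from %s\n", length(x),
              format(x$start_date)))
  invisible(x)
}

#' Sub-annual interval series
#'
#' A `years x intervals` matrix of aggregated climate values: per-interval
#' precipitation totals (mm), mean temperatures (degrees C), potential
#' evapotranspiration (mm) or net rainfall (mm). All downstream arithmetic
#' (scenario and paleo modulation, PET) operates on this container.
#'
#' @param values Numeric matrix, years in rows, intervals (12 months or 52
#'   weeks) in columns.
#' @param kind One of `"precip_total_mm"`, `"temp_mean_c"`, `"pet_mm"`,
#'   `"net_mm"`.
#' @param epoch Calendar year of the first row (signed; BCE negative,
#'   astronomical numbering). Defaults to 1.
#'
#' @return An object of class `subannual_series`.
#' @export
subannual_series <- function(values,
                             kind = c("precip_total_mm", "temp_mean_c",
                                      "pet_mm", "net_mm"),
                             epoch = 1L) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!ncol(values) %in% c(12L, 52L))
    stop("values must have 12 or 52 columns, got ", ncol(values), call. = FALSE)
  if (anyNA(values))
    stop("sub-annual series must be complete (no missing cells)", call. = FALSE)
  if (kind %in% c("precip_total_mm", "pet_mm") && any(values < 0))
    stop(kind, " values must be >= 0 everywhere", call. = FALSE)
  dimnames(values) <- NULL
  structure(
    list(values = values, kind = kind, N = ncol(values), Y = nrow(values),
         epoch = as.integer(epoch)),
    class = "subannual_series")
}

#' @export
print.subannual_series <- function(x, ...) {
  cat(sprintf("<subannual_series> %s: %d years x %d intervals (epoch %d)\n",
              x$kind, x$Y, x$N, x$epoch))
  invisible(x)
}

#' @export
dim.subannual_series <- function(x) dim(x$values)

# internal: check that two sub-annual series are conformable
check_same_shape <- function(a, b, what = "series") {
  if (!identical(dim(a$values), dim(b$values)))
    stop("shape mismatch between ", what, ": ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
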