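#' Read daily meteorological observations
#'
#' Reads a delimited text file of daily station observations into a
#' validated [daily_series()]. The default dialect expects columns
#' `date` (ISO-8601), `precip_mm`, `tmin_c`, `tmax_c`; `col_map` renames
#' columns so that e.g. MIDAS-style exports can be ingested without
#' pre-processing.
#'
#' Rows at the start or end of the file whose three value columns are all
#' missing are trimmed. Missing values in the interior are rejected by
#' default (the generator must be trained on a continuous record); with
#' `fill = "climatology"` they are replaced by the day-of-year mean over
#' the remaining years and reported via a message.
#'
#' @param path Path to a delimited text file.
#' @param col_map Optional named character vector mapping the canonical
#'   names `date`, `precip_mm`, `tmin_c`, `tmax_c` to the file's column
#'   names, e.g. `c(date = "ob_date", precip_mm = "prcp_amt")`.
#' @param fill Policy for internal missing values: `"reject"` (default) or
#'   `"climatology"`.
#' @param sep Field separator (default comma).
#' @return A [daily_series()].
#' @export
read_daily_obs <- function(path, col_map = NULL,
                           fill = c("reject", "climatology"), sep = ",") {
  fill <- match.arg(fill)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(date = "date", precip_mm = "precip_mm",
            tmin_c = "tmin_c", tmax_c = "tmax_c")
  if (!is.null(col_map)) need[names(col_map)] <- col_map
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(as.character(raw[[need[["date"]]]]), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop("malformed date at row ", bad[1L], ": '",
         raw[[need[["date"]]]][bad[1L]], "'", call. = FALSE)
  p <- as.numeric(raw[[need[["precip_mm"]]]])
  tn <- as.numeric(raw[[need[["tmin_c"]]]])
  tx <- as.numeric(raw[[need[["tmax_c"]]]])

  # trim all-missing rows at the series edges
  all_na <- is.na(p) & is.na(tn) & is.na(tx)
  keep <- which(!all_na)
  if (!length(keep)) stop("no usable rows in ", path, call. = FALSE)
  idx <- keep[1L]:keep[length(keep)]
  dates <- dates[idx]; p <- p[idx]; tn <- tn[idx]; tx <- tx[idx]

  gaps <- which(diff(as.integer(dates)) != 1L)
  if (length(gaps))
    stop("gap in daily dates between ", format(dates[gaps[1L]]), " and ",
         format(dates[gaps[1L] + 1L]), call. = FALSE)

  n_na <- sum(is.na(p)) + sum(is.na(tn)) + sum(is.na(tx))
  if (n_na > 0L) {
    if (fill == "reject") {
      row1 <- which(is.na(p) | is.na(tn) | is.na(tx))[1L]
      stop(n_na, " internal missing value(s); first at row ", row1,
           " (", format(dates[row1]), "). Use fill = 'climatology' to impute.",
           call. = FALSE)
    }
    doy <- pmin(as.integer(format(dates, "%j")), 365L)
    fill_doy <- function(x) {
      mu <- tapply(x, doy, mean, na.rm = TRUE)
      miss <- is.na(x)
      x[miss] <- mu[as.character(doy[miss])]
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    }
    p <- fill_doy(p); tn <- fill_doy(tn); tx <- fill_doy(tx)
    message("filled ", n_na, " missing value(s) with day-of-year climatology")
  }
  bad <- which(tn > tx)
  if (length(bad))
    stop("tmin_c > tmax_c at row ", bad[1L], " (", format(dates[bad[1L]]), ")",
         call. = FALSE)
  daily_series(dates[1L], p, tn, tx)
}

#' Write daily observations
#'
#' Writes a [daily_series()] as CSV in the canonical dialect read by
#' [read_daily_obs()] (columns `date`, `precip_mm`, `tmin_c`, `tmax_c`).
#'
#' @param series A [daily_series()].
#' @param path Output path.
#' @export
write_daily_obs <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  df <- data.frame(
    date = format(series$start_date + seq_len(length(series)) - 1L),
    precip_mm = series$precip_mm,
    tmin_c = series$tmin_c,
    tmax_c = series$tmax_c)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Holocene anomaly grid
#'
#' Reads a long-format table of gridded 1000-year-resolution climate
#' anomalies (columns `lon`, `lat`, `age_bp`, `dtemp_c`, `dprec_mm_day`)
#' into a collection of [anomaly_series()] objects, one per 1-degree grid
#' cell. Each cell must contribute exactly the 13 knots at ages 0, 1000,
#' ..., 12000 years BP.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A named list of [anomaly_series()], keyed `"lon,lat"` by the
#'   cell's lower-left corner.
#' @export
read_anomaly_grid <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("lon", "lat", "age_bp", "dtemp_c", "dprec_mm_day")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ages_ref <- seq(0L, 12000L, by = 1000L)
  key <- paste(raw$lon, raw$lat, sep = ",")
  out <- lapply(split(raw, key), function(d) {
    dup <- duplicated(d$age_bp)
    if (any(dup))
      stop("duplicate (cell, age) row: cell (", d$lon[1L], ",", d$lat[1L],
           ") age ", d$age_bp[dup][1L], call. = FALSE)
    missing_ages <- setdiff(ages_ref, d$age_bp)
    if (length(missing_ages))
      stop("cell (", d$lon[1L], ",", d$lat[1L], ") is missing age(s) ",
           paste(missing_ages, collapse = ", "), " BP", call. = FALSE)
    d <- d[order(d$age_bp), ]
    anomaly_series(cell = c(d$lon[1L], d$lat[1L]),
                   dT_c = d$dtemp_c, dP_mm_day = d$dprec_mm_day)
  })
  out[order(names(out))]
}

#' Write a Holocene anomaly grid
#'
#' Inverse of [read_anomaly_grid()]: writes a collection of
#' [anomaly_series()] as a long-format CSV.
#'
#' @param grid Named list of [anomaly_series()].
#' @param path Output path.
#' @export
write_anomaly_grid <- function(grid, path) {
  rows <- do.call(rbind, lapply(grid, function(a) {
    data.frame(lon = a$cell[1L], lat = a$cell[2L], age_bp = a$ages_bp,
               dtemp_c = a$dT_c, dprec_mm_day = a$dP_mm_day)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write delta-change scaler sets
#'
#' Scaler sets (per-interval additive temperature deltas and relative
#' precipitation deltas for one projection period) are stored as a single
#' long-format CSV with columns `period_start`, `period_end`, `interval`,
#' `dT_c`, `dP_rel`, so that externally computed (e.g. GCM-derived) tables
#' can bypass the climatology stage.
#'
#' @param path Path to the CSV file.
#' @return `read_scalers()` returns a list of [scaler_set()] ordered by
#'   period start year.
#' @export
read_scalers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("period_start", "period_end", "interval", "dT_c", "dP_rel")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  sets <- lapply(split(raw, raw$period_start), function(d) {
    d <- d[order(d$interval), ]
    if (!identical(d$interval, seq_len(nrow(d))))
      stop("period ", d$period_start[1L], "-", d$period_end[1L],
           ": intervals must be 1..N without gaps", call. = FALSE)
    scaler_set(period = c(d$period_start[1L], d$period_end[1L]),
               dT = d$dT_c, dP_rel = d$dP_rel)
  })
  sets[order(vapply(sets, function(s) s$period[1L], numeric(1)))]
}

#' @rdname read_scalers
#' @param sets List of [scaler_set()].
#' @export
write_scalers <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(period_start = s$period[1L], period_end = s$period[2L],
               interval = seq_along(s$dT), dT_c = s$dT, dP_rel = s$dP_rel)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sub-annual series
#'
#' Long-format CSV (`year_index`, `interval`, `value` plus constant `kind`
#' and `epoch` columns) used to pass intermediate series between pipeline
#' stages.
#'
#' @param path Path to the CSV file.
#' @return `read_subannual()` returns a [subannual_series()].
#' @export
read_subannual <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year_index", "interval", "value", "kind", "epoch")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  Y <- max(raw$year_index); N <- max(raw$interval)
  m <- matrix(NA_real_, Y, N)
  m[cbind(raw$year_index, raw$interval)] <- raw$value
  subannual_series(m, kind = raw$kind[1L], epoch = raw$epoch[1L])
}

#' @rdname read_subannual
#' @param series A [subannual_series()].
#' @export
write_subannual <- function(series, path) {
  stopifnot(inherits(series, "subannual_series"))
  df <- data.frame(
    year_index = rep(seq_len(series$Y), times = series$N),
    interval = rep(seq_len(series$N), each = series$Y),
    value = as.vector(series$values),
    kind = series$kind, epoch = series$epoch)
  df <- df[order(df$year_index, df$interval), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a climate driver file
#'
#' Writes the assembled driver (precipitation, temperature, PET and net
#' rainfall, aligned over the full run) as a delimited text file with one
#' row per (year, interval), plus a YAML sidecar (`<path>.meta.yaml`)
#' recording site, seed and configuration so any run can be reproduced
#' from its outputs alone.
#'
#' Columns: `year_index` (1-based), `calendar_year` (signed, astronomical
#' numbering; BCE negative), `interval`, `precip_mm`, `temp_c`, `pet_mm`,
#' `net_mm`.
#'
#' @param driver A `climate_driver` from [assemble_driver()].
#' @param path Output path.
#' @export
write_driver <- function(driver, path) {
  stopifnot(inherits(driver, "climate_driver"))
  dims <- lapply(driver[c("precip", "temp", "pet", "net")],
                 function(s) dim(s$values))
  if (length(unique(dims)) != 1L)
    stop("driver series are misaligned: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "),
         call. = FALSE)
  Y <- driver$precip$Y; N <- driver$precip$N
  yi <- rep(seq_len(Y), each = N)
  df <- data.frame(
    year_index = yi,
    calendar_year = driver$epoch + yi - 1L,
    interval = rep(seq_len(N), times = Y),
    precip_mm = as.vector(t(driver$precip$values)),
    temp_c = as.vector(t(driver$temp$values)),
    pet_mm = as.vector(t(driver$pet$values)),
    net_mm = as.vector(t(driver$net$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(site = unclass(driver$site), seed = driver$seed,
               config = driver$config)
  writeLines(yaml::as.yaml(meta), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a climate driver file
#'
#' Inverse of [write_driver()]; reads the driver table (and, if present,
#' its metadata sidecar) back into a `climate_driver`.
#'
#' @param path Path written by [write_driver()].
#' @export
read_driver <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  Y <- max(raw$year_index); N <- max(raw$interval)
  epoch <- raw$calendar_year[1L] - raw$year_index[1L] + 1L
  grab <- function(col, kind) {
    m <- matrix(NA_real_, Y, N)
    m[cbind(raw$year_index, raw$interval)] <- raw[[col]]
    subannual_series(m, kind = kind, epoch = epoch)
  }
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  site <- if (!is.null(meta$site))
    site_meta(meta$site$name, meta$site$lat, meta$site$lon,
              meta$site$elevation_m)
  else site_meta("unknown", 0, 0, 0)
  structure(
    list(site = site,
         precip = grab("precip_mm", "precip_total_mm"),
         temp = grab("temp_c", "temp_mean_c"),
         pet = grab("pet_mm", "pet_mm"),
         net = grab("net_mm", "net_mm"),
         epoch = epoch, seed = meta$seed, config = meta$config),
    class = "climate_driver")
}
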