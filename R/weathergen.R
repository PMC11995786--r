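# Stochastic daily weather generator.
#
# The occurrence process is an alternating renewal process of dry and wet
# spells whose lengths are drawn from per-month semi-empirical (histogram)
# distributions; a spell is attributed to the month in which it starts.
# Wet-day precipitation amounts come from a per-month empirical quantile
# function. Daily minimum and maximum temperatures are normal,
# conditioned on the day being wet or dry, with seasonal mean and
# standard deviation described by third-order finite Fourier series over
# the 365-day year and lag-1 autocorrelated residuals.

# ---- Fourier seasonal curves -------------------------------------------

fourier_basis <- function(d) {
  ang <- 2 * pi * outer(d, 1:3) / 365
  cbind(1, cos(ang[, 1L]), sin(ang[, 1L]),
        cos(ang[, 2L]), sin(ang[, 2L]),
        cos(ang[, 3L]), sin(ang[, 3L]))
}

fit_fourier <- function(d, y) {
  if (length(y) < 8L) return(c(mean(y), rep(0, 6)))
  qr.coef(qr(fourier_basis(d)), y)
}

eval_fourier <- function(coef, d = 1:365) {
  drop(fourier_basis(d) %*% coef)
}

# ---- fitting ------------------------------------------------------------

# day-of-year on a 365-day calendar (Feb 29 folded onto Feb 28)
doy365 <- function(dates) {
  mdays <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  cum <- c(0L, cumsum(mdays))[1:12]
  m <- as.integer(format(dates, "%m"))
  day <- pmin(as.integer(format(dates, "%d")), mdays[m])
  cum[m] + day
}

#' Fit the stochastic weather generator
#'
#' Estimates, from a continuous daily observation record, all components
#' of the generator: per-month dry- and wet-spell length histograms,
#' per-month wet-day amount distributions, wet/dry-conditioned
#' third-order Fourier seasonal curves for the mean and standard
#' deviation of tmin and tmax, the lag-1 autocorrelation of the
#' standardised temperature residuals, and the tmin/tmax residual
#' cross-correlation used for joint draws.
#'
#' A month with zero wet days across all years triggers a
#' degenerate-distribution warning and yields a point-mass dry model for
#' that month (simulations never place a wet day there). At least one
#' full year of data is required; ten or more years are recommended for a
#' stable fit.
#'
#' @param obs A [daily_series()] of observations (>= 365 days).
#' @param wet_threshold_mm A day is wet when `precip > wet_threshold_mm`
#'   (default 0.1 mm, the usual trace-rain convention).
#' @param n_bins Number of histogram bins for the spell-length
#'   distributions (default 23).
#' @return An object of class `weathergen_model`.
#' @export
fit_weathergen <- function(obs, wet_threshold_mm = 0.1, n_bins = 23L) {
  stopifnot(inherits(obs, "daily_series"))
  n <- length(obs)
  dates <- obs$start_date + seq_len(n) - 1L
  month <- as.integer(format(dates, "%m"))
  d365 <- doy365(dates)
  wet <- obs$precip_mm > wet_threshold_mm

  # spells, attributed to the month of their first day
  r <- rle(wet)
  spell_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  spell_month <- month[spell_start]
  spells <- data.frame(len = r$lengths, wet = r$values, month = spell_month)

  months <- vector("list", 12L)
  degenerate <- integer(0)
  for (m in 1:12) {
    dl <- spells$len[!spells$wet & spells$month == m]
    wl <- spells$len[spells$wet & spells$month == m]
    am <- obs$precip_mm[wet & month == m]
    if (!length(am) && any(month == m)) degenerate <- c(degenerate, m)
    months[[m]] <- list(dry = fit_spell_dist(dl, n_bins),
                        wet = fit_spell_dist(wl, n_bins),
                        amounts = fit_amount_dist(am))
  }
  if (length(degenerate))
    warning("month(s) ", paste(degenerate, collapse = ", "),
            " have zero wet days: point-mass dry model used there",
            call. = FALSE)
  global <- list(dry = fit_spell_dist(spells$len[!spells$wet], n_bins),
                 wet = fit_spell_dist(spells$len[spells$wet], n_bins),
                 amounts = fit_amount_dist(obs$precip_mm[wet]))

  # temperature: wet/dry-conditioned seasonal normal model
  fit_var <- function(x) {
    uncond_mu <- fit_fourier(d365, x)
    cond <- lapply(c(wet = TRUE, dry = FALSE), function(w) {
      sel <- wet == w
      mu_coef <- if (sum(sel) >= 30L) fit_fourier(d365[sel], x[sel]) else uncond_mu
      resid <- x[sel] - eval_fourier(mu_coef, d365[sel])
      sd_m <- tapply(resid, factor(month[sel], levels = 1:12), stats::sd)
      ok <- !is.na(sd_m) & sd_m > 0
      J <- make_calendar(12)$julian_mid
      sd_coef <- if (sum(ok) >= 8L) fit_fourier(J[ok], sd_m[ok])
      else c(max(stats::sd(resid), 0.1), rep(0, 6))
      list(mu_coef = mu_coef, sd_coef = sd_coef)
    })
    # standardised residuals in time order, for lag-1 autocorrelation
    mu_day <- ifelse(wet, eval_fourier(cond$wet$mu_coef, d365),
                     eval_fourier(cond$dry$mu_coef, d365))
    sd_day <- ifelse(wet,
                     pmax(eval_fourier(cond$wet$sd_coef, d365), 0.05),
                     pmax(eval_fourier(cond$dry$sd_coef, d365), 0.05))
    z <- (x - mu_day) / sd_day
    r1 <- if (length(z) > 2L)
      suppressWarnings(stats::cor(z[-1L], z[-length(z)])) else 0
    if (!is.finite(r1)) r1 <- 0   # e.g. constant record
    list(wet = cond$wet, dry = cond$dry,
         lag1 = max(min(r1, 0.95), -0.95), z = z)
  }
  tmin_fit <- fit_var(obs$tmin_c)
  tmax_fit <- fit_var(obs$tmax_c)
  rho <- suppressWarnings(stats::cor(tmin_fit$z, tmax_fit$z))
  if (!is.finite(rho)) rho <- 0
  tmin_fit$z <- NULL; tmax_fit$z <- NULL

  structure(
    list(wet_threshold_mm = wet_threshold_mm, n_bins = as.integer(n_bins),
         months = months, global = global, dry_months = degenerate,
         tmin = tmin_fit, tmax = tmax_fit,
         cross_corr = max(min(rho, 0.999), -0.999),
         n_days_fit = n),
    class = "weathergen_model")
}

#' @export
print.weathergen_model <- function(x, ...) {
  wf <- mean(vapply(x$months, function(m) m$amounts$n, numeric(1))) /
    (x$n_days_fit / 12)
  cat(sprintf(paste0("<weathergen_model> fitted on %d days ",
                     "(wet threshold %.2f mm, mean wet fraction %.2f)\n"),
              x$n_days_fit, x$wet_threshold_mm, wf))
  invisible(x)
}

# seasonal curves evaluated on the 365-day year, clamped so the sd stays
# strictly positive
wg_curves <- function(var_fit) {
  list(mu_wet = eval_fourier(var_fit$wet$mu_coef),
       mu_dry = eval_fourier(var_fit$dry$mu_coef),
       sd_wet = pmax(eval_fourier(var_fit$wet$sd_coef), 0.05),
       sd_dry = pmax(eval_fourier(var_fit$dry$sd_coef), 0.05))
}

# ---- simulation ---------------------------------------------------------

#' Simulate daily weather from a fitted generator
#'
#' Produces `n_years` of synthetic daily weather on a 365-day calendar
#' (no leap days). Occurrence is simulated as alternating dry/wet spells
#' drawn from the monthly histogram distributions of the current day's
#' month; wet-day amounts from the monthly empirical quantile functions;
#' temperatures from the wet/dry-conditioned seasonal normal model with
#' AR(1) residuals, tmin and tmax drawn jointly with their fitted
#' residual cross-correlation. If a draw yields `tmin > tmax` the day's
#' innovations are redrawn (up to 100 times, then the pair is swapped) so
#' the output always satisfies the daily-series invariants.
#'
#' The output is bit-reproducible for a fixed `(model, n_years, seed)`.
#'
#' @param model A [fit_weathergen()] model.
#' @param n_years Number of 365-day years to simulate (>= 1).
#' @param seed Integer RNG seed.
#' @return A [daily_series()] of length `365 * n_years` (nominal start
#'   date 2001-01-01; simulated years are abstract 365-day years).
#' @export
simulate_daily <- function(model, n_years, seed = 1L) {
  stopifnot(inherits(model, "weathergen_model"), n_years >= 1L)
  n_days <- n_years * 365
  if (n_days > .Machine$integer.max)
    stop("series of ", n_years, " years overflows the day index", call. = FALSE)
  n_days <- as.integer(n_days)
  set.seed(seed, kind = "Mersenne-Twister")
  month_of_day <- make_calendar(12)$interval_of_day

  wet <- simulate_occurrence(model, n_days, month_of_day)

  # wet-day amounts, drawn per month (global fallback where a spell runs
  # into a month that had no wet days in training)
  precip <- numeric(n_days)
  widx <- which(wet)
  if (length(widx)) {
    wmon <- month_of_day[(widx - 1L) %% 365L + 1L]
    for (m in sort(unique(wmon))) {
      sel <- widx[wmon == m]
      dist <- model$months[[m]]$amounts
      if (dist$n == 0L) dist <- model$global$amounts
      precip[sel] <- sample_amount_dist(dist, length(sel))
    }
  }

  tt <- simulate_temperature(model, n_days, wet)
  daily_series(as.Date("2001-01-01"), precip, tt$tmin, tt$tmax)
}

# alternating dry/wet spell chain; returns logical wet flag per day.
# Spell lengths are consumed from pre-drawn per-(state, month) pools so
# the sequential chain stays cheap even over millions of days.
simulate_occurrence <- function(model, n_days, month_of_day) {
  # all-dry degenerate model
  if (model$global$wet$n == 0L) return(logical(n_days))

  # slots 1..12 = dry by month, 13..24 = wet by month
  dists <- vector("list", 24L)
  dead <- logical(24L)   # no spell can start (degenerate or distribution-less)
  for (m in 1:12) {
    d <- model$months[[m]]$dry
    if (d$n == 0L) d <- model$global$dry
    dists[[m]] <- d
    dead[m] <- d$n == 0L  # all-wet record: dry spells absent everywhere
    w <- model$months[[m]]$wet
    if (w$n == 0L) w <- model$global$wet
    dists[[12L + m]] <- w
    dead[12L + m] <- w$n == 0L || m %in% model$dry_months
  }

  chunk <- 16384L
  pool <- vector("list", 24L)
  cnt <- integer(24L); pool_len <- integer(24L)

  s_wet <- logical(n_days + 1L); s_len <- integer(n_days + 1L)
  k <- 0L; pos <- 1L; state_wet <- FALSE
  while (pos <= n_days) {
    j <- month_of_day[(pos - 1L) %% 365L + 1L]
    if (state_wet) j <- j + 12L
    if (dead[j]) { state_wet <- !state_wet; next }
    i <- cnt[j] + 1L
    if (i > pool_len[j]) {
      pool[[j]] <- sample_spell_dist(dists[[j]], chunk)
      pool_len[j] <- chunk
      i <- 1L
    }
    cnt[j] <- i
    len <- pool[[j]][i]
    if (len > n_days - pos + 1L) len <- n_days - pos + 1L
    k <- k + 1L
    s_wet[k] <- state_wet; s_len[k] <- len
    pos <- pos + len
    state_wet <- !state_wet
  }
  rep(s_wet[seq_len(k)], s_len[seq_len(k)])
}

# wet/dry-conditioned seasonal normal temperatures with AR(1) residuals
simulate_temperature <- function(model, n_days, wet) {
  doy <- rep_len(1:365, n_days)
  cmin <- wg_curves(model$tmin); cmax <- wg_curves(model$tmax)
  wd <- which(wet); doy_w <- doy[wd]
  pick <- function(curves, dry_curve, wet_curve) {
    out <- curves[[dry_curve]][doy]
    out[wd] <- curves[[wet_curve]][doy_w]
    out
  }
  mu_min <- pick(cmin, "mu_dry", "mu_wet"); sd_min <- pick(cmin, "sd_dry", "sd_wet")
  mu_max <- pick(cmax, "mu_dry", "mu_wet"); sd_max <- pick(cmax, "sd_dry", "sd_wet")

  rho <- model$cross_corr
  r_min <- model$tmin$lag1; r_max <- model$tmax$lag1
  z1 <- stats::rnorm(n_days); z2 <- stats::rnorm(n_days)
  e_max <- z1
  e_min <- rho * z1 + sqrt(1 - rho^2) * z2
  x_min <- as.numeric(stats::filter(sqrt(1 - r_min^2) * e_min, r_min,
                                    method = "recursive"))
  x_max <- as.numeric(stats::filter(sqrt(1 - r_max^2) * e_max, r_max,
                                    method = "recursive"))
  tmin <- mu_min + sd_min * x_min
  tmax <- mu_max + sd_max * x_max

  # enforce tmin <= tmax: redraw violating days' innovations locally
  # (previous-day residual states kept), then swap as a last resort
  vi <- which(tmin > tmax)
  tries <- 0L
  while (length(vi) && tries < 100L) {
    zp1 <- stats::rnorm(length(vi)); zp2 <- stats::rnorm(length(vi))
    emx <- zp1; emn <- rho * zp1 + sqrt(1 - rho^2) * zp2
    prev <- vi - 1L
    xp_min <- ifelse(prev >= 1L, x_min[pmax(prev, 1L)], 0)
    xp_max <- ifelse(prev >= 1L, x_max[pmax(prev, 1L)], 0)
    nx_min <- r_min * xp_min + sqrt(1 - r_min^2) * emn
    nx_max <- r_max * xp_max + sqrt(1 - r_max^2) * emx
    cand_min <- mu_min[vi] + sd_min[vi] * nx_min
    cand_max <- mu_max[vi] + sd_max[vi] * nx_max
    ok <- cand_min <= cand_max
    tmin[vi[ok]] <- cand_min[ok]; tmax[vi[ok]] <- cand_max[ok]
    vi <- vi[!ok]
    tries <- tries + 1L
  }
  if (length(vi)) {
    tmp <- tmin[vi]; tmin[vi] <- tmax[vi]; tmax[vi] <- tmp
  }
  list(tmin = tmin, tmax = tmax)
}

# ---- serialization ------------------------------------------------------

#' Save / load a fitted weather generator
#'
#' The model is written as a single human-readable YAML file (histogram
#' breaks and probabilities, quantile tables, Fourier coefficients,
#' correlations) so fits can be inspected, versioned and reused.
#'
#' @param model A `weathergen_model`.
#' @param path File path.
#' @return `read_weathergen()` returns the restored `weathergen_model`.
#' @export
write_weathergen <- function(model, path) {
  stopifnot(inherits(model, "weathergen_model"))
  plainify <- function(x) {
    if (is.list(x)) return(lapply(x, plainify))
    if (is.numeric(x)) return(as.numeric(x))
    x
  }
  obj <- plainify(unclass(model))
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname write_weathergen
#' @export
read_weathergen <- function(path) {
  obj <- yaml::read_yaml(path)
  reclass_dist <- function(d, cls) {
    d <- lapply(d, function(v) if (is.list(v)) unlist(v) else v)
    if (is.null(d$breaks) && cls == "semiempirical") d$breaks <- numeric(0)
    if (is.null(d$probs) && cls == "semiempirical") d$probs <- numeric(0)
    if (is.null(d$q) && cls == "empquant") d$q <- numeric(0)
    d$n <- as.integer(d$n)
    structure(d, class = cls)
  }
  fix_month <- function(m) {
    list(dry = reclass_dist(m$dry, "semiempirical"),
         wet = reclass_dist(m$wet, "semiempirical"),
         amounts = reclass_dist(m$amounts, "empquant"))
  }
  fix_var <- function(v) {
    list(wet = list(mu_coef = unlist(v$wet$mu_coef),
                    sd_coef = unlist(v$wet$sd_coef)),
         dry = list(mu_coef = unlist(v$dry$mu_coef),
                    sd_coef = unlist(v$dry$sd_coef)),
         lag1 = v$lag1)
  }
  structure(
    list(wet_threshold_mm = obj$wet_threshold_mm,
         n_bins = as.integer(obj$n_bins),
         months = lapply(obj$months, fix_month),
         global = fix_month(obj$global),
         dry_months = as.integer(unlist(obj$dry_months)),
         tmin = fix_var(obj$tmin), tmax = fix_var(obj$tmax),
         cross_corr = obj$cross_corr,
         n_days_fit = as.integer(obj$n_days_fit)),
    class = "weathergen_model")
}
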