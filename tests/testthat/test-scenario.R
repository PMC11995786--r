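test_that("interval climatology is the per-interval mean over years", {
  one <- subannual_series(matrix(3.5, 1, 12), "temp_mean_c")
  expect_equal(interval_climatology(one)$values, rep(3.5, 12))

  set.seed(101)
  m <- matrix(rnorm(100 * 12, 10, 3), 100, 12)
  s <- subannual_series(m, "temp_mean_c")
  # brute-force column-mean oracle
  oracle <- vapply(1:12, function(j) sum(m[, j]) / 100, numeric(1))
  expect_equal(interval_climatology(s)$values, oracle, tolerance = 1e-12)
})

test_that("temperature scalers are signed differences, precipitation relative", {
  clim <- function(v) structure(list(N = length(v), values = v, kind = "x"),
                                class = "interval_climatology")
  expect_equal(temp_scalers(clim(c(5, 10)), clim(c(5, 10))), c(0, 0))
  expect_equal(temp_scalers(clim(c(5, 10)), clim(c(6, 12))), c(1, 2))
  expect_equal(temp_scalers(clim(10), clim(8)), -2)   # cooling allowed

  expect_equal(precip_scalers(clim(100), clim(100)), 0)
  expect_equal(precip_scalers(clim(100), clim(90)), -0.10)
  expect_equal(precip_scalers(clim(50), clim(75)), 0.50)
  expect_error(precip_scalers(clim(0), clim(10)), "interval 1")
  expect_error(temp_scalers(clim(1:3), clim(1:2)), "interval counts")
})

test_that("scaler interpolation reproduces knots and holds beyond the last", {
  sets <- make_synthetic_scalers(dT_final = seq(0.5, 6, length.out = 12),
                                 dP_rel_final = seq(-0.2, 0.2,
                                                    length.out = 12))
  traj <- interpolate_scalers(sets, horizon_years = 100)
  # exact knot reproduction at the anchor times
  at_knots <- traj$at(traj$anchors)
  expect_equal(at_knots$dT, traj$knots_dT, tolerance = 1e-12)
  expect_equal(at_knots$dP_rel, traj$knots_dP, tolerance = 1e-12)
  # held constant beyond the final anchor (years 91..100 for 2081-2100)
  for (y in 91:100)
    expect_equal(traj$dT[y, ], sets[[7]]$dT, tolerance = 1e-12)
  # zero at year-0 anchor ensures a smooth ramp from the baseline
  expect_equal(traj$at(0)$dT[1, ], rep(0, 12), tolerance = 1e-12)
})

test_that("all-zero scalers interpolate to an all-zero trajectory", {
  sets <- list(scaler_set(c(2021, 2040), rep(0, 12), rep(0, 12)))
  traj <- interpolate_scalers(sets, horizon_years = 50)
  expect_true(all(traj$dT == 0))
  expect_true(all(traj$dP_rel == 0))
})

test_that("linear knots interpolate to the straight line", {
  # knots rising linearly across period midpoints, zero-anchored at 0:
  # midpoints 2030.5 + 10k -> years 30.5, 40.5, ..., 90.5
  slope <- 0.04
  sets <- lapply(1:7, function(i)
    scaler_set(c(2021 + 10 * (i - 1), 2040 + 10 * (i - 1)),
               dT = rep(slope * (30.5 + 10 * (i - 1)), 12),
               dP_rel = rep(0, 12)))
  traj <- interpolate_scalers(sets, horizon_years = 100)
  years <- 1:100
  expected <- slope * pmin(years, 90.5)   # clamped past the last anchor
  for (n in c(1L, 7L, 12L))
    expect_equal(traj$dT[, n], expected, tolerance = 1e-9)
})

test_that("each interval's trajectory depends only on its own knots", {
  base <- make_synthetic_scalers(dT_final = rep(2, 12))
  bumped <- lapply(base, function(s) {
    s$dT[4] <- s$dT[4] + 1
    s
  })
  t1 <- interpolate_scalers(base, horizon_years = 60)
  t2 <- interpolate_scalers(bumped, horizon_years = 60)
  expect_false(isTRUE(all.equal(t1$dT[, 4], t2$dT[, 4])))
  expect_equal(t1$dT[, -4], t2$dT[, -4], tolerance = 1e-12)
})

test_that("applying scalers modulates the tail elementwise", {
  set.seed(7)
  P <- subannual_series(matrix(runif(20 * 12, 20, 120), 20, 12),
                        "precip_total_mm")
  Tm <- subannual_series(matrix(rnorm(20 * 12, 8, 3), 20, 12), "temp_mean_c")

  zero <- interpolate_scalers(
    list(scaler_set(c(2021, 2040), rep(0, 12), rep(0, 12))),
    horizon_years = 20)
  out <- apply_scenario(P, Tm, zero)
  expect_identical(out$precip$values, P$values)
  expect_identical(out$temp$values, Tm$values)

  warm <- zero; warm$dT[] <- 2; warm$dP_rel[] <- -0.5
  out2 <- apply_scenario(P, Tm, warm)
  expect_equal(out2$temp$values, Tm$values + 2, tolerance = 1e-12)
  expect_equal(out2$precip$values, P$values / 2, tolerance = 1e-12)

  short <- subannual_series(matrix(1, 5, 12), "precip_total_mm")
  shortT <- subannual_series(matrix(1, 5, 12), "temp_mean_c")
  expect_error(apply_scenario(short, shortT, zero), "does not match")
})

test_that("null scalers computed from identical climatologies are a no-op", {
  set.seed(11)
  base_s <- subannual_series(matrix(runif(50 * 12, 30, 150), 50, 12),
                             "precip_total_mm")
  clim <- interval_climatology(base_s)
  expect_equal(temp_scalers(clim, clim), rep(0, 12))
  expect_equal(precip_scalers(clim, clim), rep(0, 12))
})
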