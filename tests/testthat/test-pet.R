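test_that("heat index is interval-invariant and handles sub-zero input", {
  expect_equal(heat_index(rep(5, 12)), 12)
  expect_equal(heat_index(rep(5, 52)), 12)     # the 12/N factor at work
  expect_equal(heat_index(rep(10, 12)), 34.2720955124415, tolerance = 1e-12)
  expect_equal(heat_index(rep(-10, 12)), 0)    # negatives contribute nothing
  expect_equal(heat_index(c(rep(-3, 6), rep(5, 6))),
               heat_index(c(rep(0, 6), rep(5, 6))))
})

test_that("the Thornthwaite exponent matches its polynomial", {
  expect_equal(exponent_a(0), 0.49239)
  expect_equal(exponent_a(100), 2.18839, tolerance = 1e-12)
  expect_equal(exponent_a(34.2720955124415), 1.04315836041644,
               tolerance = 1e-12)
})

test_that("unscaled PET follows the power law", {
  expect_equal(pet_unscaled(0, 30), 0)
  expect_equal(pet_unscaled(-5, 30), 0)
  expect_equal(pet_unscaled(3, 30), 16)      # 10 t = I -> base 1
  expect_equal(pet_unscaled(10, 34.2720955124415), 48.8934318685646,
               tolerance = 1e-9)
  expect_error(pet_unscaled(5, 0), "inconsistent")
})

test_that("solar declination and day length behave at reference points", {
  expect_equal(solar_declination(81), 0)
  expect_equal(solar_declination(172), 23.4497828468137, tolerance = 1e-10)
  expect_equal(solar_declination(355), -23.4497828468137, tolerance = 1e-10)

  expect_equal(day_length(58.288, 0), 12)         # equinox
  expect_equal(day_length(0, 17.3), 12)           # equator, any declination
  expect_equal(day_length(58.454, -23.45), 6.00566019177235,
               tolerance = 1e-9)
  # polar clamping instead of domain errors
  expect_equal(day_length(85, 23.45), 24)
  expect_equal(day_length(85, -23.45), 0)
})

test_that("PET scaling corrects the 30-day 12-hour reference", {
  expect_equal(scale_pet(48.9, 12, 30), 48.9)
  expect_equal(scale_pet(48.9, 6, 30), 24.45)
  expect_equal(scale_pet(48.9, 12, 7), 11.41, tolerance = 1e-9)
})

test_that("PET component formulas match independent evaluations", {
  # straight-loop re-evaluations, checked at 1e-9 relative error
  set.seed(314)
  for (i in 1:250) {
    t <- stats::runif(12, -5, 30)
    I <- 0
    for (x in t) I <- I + (max(x, 0) / 5)^1.514
    I <- I * (12 / 12)
    expect_equal(heat_index(t), I, tolerance = 1e-9)
    a_ref <- 675e-9 * I^3 - 771e-7 * I^2 + 1792e-5 * I + 0.49239
    expect_equal(exponent_a(I), a_ref, tolerance = 1e-9)
    lat <- stats::runif(1, -66, 66)
    J <- sample.int(365, 1)
    d_ref <- 23.45 * sinpi(((J - 81) * 360 / 365) / 180)
    L_ref <- (24 / pi) * acos(-tanpi(lat / 180) * tanpi(d_ref / 180))
    expect_equal(day_length(lat, solar_declination(J)), L_ref,
                 tolerance = 1e-9)
    if (I > 0) {
      tn <- stats::runif(1, 0.5, 30)
      pet_ref <- 16 * (10 * tn / I)^a_ref * (L_ref / 12) * (28 / 30)
      expect_equal(scale_pet(pet_unscaled(tn, I), L_ref, 28), pet_ref,
                   tolerance = 1e-9)
    }
  }
})

test_that("PET series compose the steps per year and stay aligned", {
  cal <- make_calendar(12)
  site_eq <- site_meta("equator", 0, 0)

  frozen <- subannual_series(matrix(-2, 3, 12), "temp_mean_c")
  expect_true(all(pet_series(frozen, site_eq, cal)$values == 0))

  warm <- subannual_series(matrix(10, 2, 12), "temp_mean_c")
  pet <- pet_series(warm, site_eq, cal)
  expect_equal(dim(pet$values), c(2L, 12L))
  # constant 10 C at the equator: 48.893... scaled by D_n/30 (L = 12 h)
  expect_equal(pet$values[1, ], 48.8934318685646 * cal$days / 30,
               tolerance = 1e-6)
})

test_that("warming a whole year never decreases annual PET", {
  cal <- make_calendar(12)
  site_eq <- site_meta("equator", 0, 0)
  set.seed(99)
  for (i in 1:100) {
    t <- stats::runif(12, 0, 30)
    y1 <- sum(pet_series(subannual_series(matrix(t, 1), "temp_mean_c"),
                         site_eq, cal)$values)
    y2 <- sum(pet_series(subannual_series(matrix(t + 1, 1), "temp_mean_c"),
                         site_eq, cal)$values)
    expect_gte(y2, y1)
    # single-interval warming: the heat-index coupling can shave a tiny
    # amount off other intervals, but never more than 0.1% of the total
    t3 <- t; j <- sample.int(12, 1); t3[j] <- t3[j] + 1
    y3 <- sum(pet_series(subannual_series(matrix(t3, 1), "temp_mean_c"),
                         site_eq, cal)$values)
    expect_gt(y3, y1 - 0.001 * y1)
  }
})

test_that("net rainfall is the elementwise water balance", {
  P <- subannual_series(matrix(50, 2, 12), "precip_total_mm")
  pet0 <- subannual_series(matrix(0, 2, 12), "pet_mm")
  expect_equal(net_rainfall(P, pet0)$values, P$values)

  pet_eq <- subannual_series(matrix(50, 2, 12), "pet_mm")
  expect_true(all(net_rainfall(P, pet_eq)$values == 0))

  pet60 <- subannual_series(matrix(60, 2, 12), "pet_mm")
  expect_true(all(net_rainfall(P, pet60)$values == -10))

  bad <- subannual_series(matrix(1, 3, 12), "pet_mm")
  expect_error(net_rainfall(P, bad), "shape mismatch")
})
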