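test_that("APD90 of a synthetic trapezoidal AP matches hand geometry", {
  # rest -85 mV, instant rise to +35 at t = 5, plateau, linear fall over
  # [205, 245]; amplitude w.r.t. zero = 35, 10% level = +3.5 mV.
  # The fall crosses 3.5 at 205 + 40 * (35 - 3.5) / (35 + 85) = 215.5 ms,
  # activation at the rise (t = 5) -> APD = 210.5 ms.
  tt <- seq(0, 300, by = 0.1)
  v <- ifelse(tt < 5, -85,
              ifelse(tt <= 205, 35,
                     ifelse(tt <= 245, 35 - (35 + 85) * (tt - 205) / 40, -85)))
  b <- ap_biomarkers(tibble::tibble(time = tt, v = v))
  expect_equal(b$apd90, 210.5, tolerance = 0.1)
  expect_equal(b$apa, 35)
  expect_equal(b$rmp, -85)
  # conventional 90%-repolarisation variant: level = 35 - 0.9*120 = -73,
  # crossed at 205 + 40 * 108 / 120 = 241 -> APD = 236
  b90 <- ap_biomarkers(tibble::tibble(time = tt, v = v), apd_method = "repol90")
  expect_equal(b90$apd90, 236, tolerance = 0.1)
})

test_that("a flat trace yields a negative APA and no APD", {
  tt <- seq(0, 100, 0.5)
  b <- ap_biomarkers(tibble::tibble(time = tt, v = rep(-85, length(tt))))
  expect_lt(b$apa, 0)
  expect_true(is.na(b$apd90))
})

test_that("exclusion applies the three criteria in printed order", {
  ok <- tibble::tibble(apd90 = 220, apa = 52, rmp = -85, upstroke_time = 2)
  expect_true(exclude_model(ok)$accepted)
  expect_equal(exclude_model(transform(ok, apa = -5))$reason, "apa")
  expect_equal(exclude_model(transform(ok, rmp = -60))$reason, "rmp")
  expect_equal(exclude_model(transform(ok, upstroke_time = 12))$reason,
               "upstroke")
  # APA failure wins over simultaneous RMP failure
  expect_equal(exclude_model(transform(ok, apa = -5, rmp = -60))$reason, "apa")
})

test_that("calibration uses closed intervals at both cycle lengths", {
  expect_true(calibrate_model(c("430" = 220, "600" = 250)))
  expect_false(calibrate_model(c("430" = 150, "600" = 250)))
  expect_true(calibrate_model(c("430" = 170, "600" = 290))) # on the bounds
  expect_false(calibrate_model(c("430" = 241, "600" = 250)))
  expect_error(calibrate_model(c("430" = 220)),
               class = "pecgsim_invalid_parameter")
})

test_that("conduction velocity follows the two-point definition", {
  sol <- structure(list(
    time = seq(0, 50, by = 0.5),
    v = outer(seq(0, 50, 0.5), seq(0, 2, 0.02),
              function(t, x) ifelse(t > 10 + (x - 0.4) / 0.06, 20, -80)),
    x = seq(0, 2, 0.02), geometry = cable_geometry()),
    class = "cable_solution")
  cvm <- conduction_velocity(sol)
  # AT(1.6) - AT(0.4) = 1.2 cm / 0.06 cm/ms -> 20 ms -> 60 cm/s
  expect_equal(cvm$cv, 60, tolerance = 0.05)
  # degenerate: simultaneous activation
  sol$v[] <- 20
  expect_error(conduction_velocity(sol), class = "pecgsim_propagation_failure")
  sol$v[] <- -80
  expect_error(conduction_velocity(sol), class = "pecgsim_propagation_failure")
})
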