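test_that("triangular waves are delineated by similar-triangles geometry", {
  # QRS: triangle peaking 1.0 at 25 ms over [10, 40]; 10% crossings at
  # 10 + 0.1*15 = 11.5 and 40 - 0.1*15 = 38.5. T: peak 0.5 at 230 over
  # [200, 260]; with the T threshold referenced to its own peak (0.05) the
  # flanks cross at 203 and 257; referenced to the QRS peak (0.1) they
  # cross at 206 and 254.
  dw <- delineate_pecg(triangle_pecg(), t_reference = "wave")
  expect_equal(dw$qrs_onset, 11.5, tolerance = 0.1)
  expect_equal(dw$qrs_end, 38.5, tolerance = 0.1)
  expect_equal(dw$qrs_duration, 27, tolerance = 0.2)
  expect_equal(dw$t_onset, 203, tolerance = 0.1)
  expect_equal(dw$t_end, 257, tolerance = 0.1)
  expect_equal(dw$qt_interval, 257 - 11.5, tolerance = 0.2)
  expect_equal(dw$t_duration, 54, tolerance = 0.2)
  expect_equal(dw$qrs_amplitude, 1, tolerance = 1e-6)
  expect_equal(dw$t_amplitude, 0.5, tolerance = 1e-6)
  expect_equal(dw$st_deviation, 0, tolerance = 1e-12)
  dq <- delineate_pecg(triangle_pecg())
  expect_equal(dq$qrs_onset, 11.5, tolerance = 0.1)
  expect_equal(dq$t_onset, 206, tolerance = 0.1)
  expect_equal(dq$t_end, 254, tolerance = 0.1)
  expect_equal(dq$t_duration, 48, tolerance = 0.2)
})

test_that("delineation is invariant to amplitude scaling except amplitudes", {
  tr <- triangle_pecg()
  d1 <- delineate_pecg(tr)
  tr$phi <- 7 * tr$phi
  d2 <- delineate_pecg(tr)
  for (f in c("qrs_duration", "qt_interval", "t_duration")) {
    expect_equal(d2[[f]], d1[[f]], tolerance = 1e-9, label = f)
  }
  expect_equal(d2$qrs_amplitude, 7 * d1$qrs_amplitude)
  expect_equal(d2$t_amplitude, 7 * d1$t_amplitude)
  expect_equal(d2$st_deviation, 7 * d1$st_deviation)
})

test_that("time shifts move landmarks but preserve durations", {
  tr <- triangle_pecg()
  d1 <- delineate_pecg(tr)
  tr2 <- tr
  tr2$time <- tr2$time + 15
  d2 <- delineate_pecg(tr2)
  expect_equal(d2$qrs_onset, d1$qrs_onset + 15, tolerance = 1e-9)
  expect_equal(d2$t_end, d1$t_end + 15, tolerance = 1e-9)
  expect_equal(d2$qrs_duration, d1$qrs_duration, tolerance = 1e-9)
  expect_equal(d2$qt_interval, d1$qt_interval, tolerance = 1e-9)
  expect_equal(d2$t_duration, d1$t_duration, tolerance = 1e-9)
})

test_that("an inverted T wave is located on |phi| with its sign preserved", {
  tr <- triangle_pecg(t_pk = -0.6)
  d <- delineate_pecg(tr, t_reference = "wave")
  expect_equal(d$t_amplitude, -0.6, tolerance = 1e-6)
  expect_equal(d$t_onset, 203, tolerance = 0.1)
  expect_equal(d$t_end, 257, tolerance = 0.1)
  # QRS-referenced threshold 0.1: crossings at 205 and 255
  dq <- delineate_pecg(tr)
  expect_equal(dq$t_amplitude, -0.6, tolerance = 1e-6)
  expect_equal(dq$t_onset, 205, tolerance = 0.1)
  expect_equal(dq$t_end, 255, tolerance = 0.1)
})

test_that("flat or single-wave traces raise delineation errors", {
  tt <- seq(0, 400, 0.5)
  expect_error(delineate_pecg(tibble::tibble(time = tt, phi = rep(0, length(tt)))),
               class = "pecgsim_delineation_error")
})

test_that("QT is never shorter than the QRS duration on simulated beats", {
  d <- delineate_pecg(compute_pecg(short_cable()))
  expect_gte(d$qt_interval, d$qrs_duration)
  expect_gte(d$t_duration, 0)
})

test_that("ratios of change follow the elementwise definition", {
  b <- tibble::tibble(qrs_duration = 20, qt_interval = 280, st_deviation = -0.4,
                      t_duration = 35, qrs_amplitude = 18, t_amplitude = -4)
  r <- ratio_of_change(b, b)
  expect_true(all(unlist(r[paste0(pecg_feature_names(), "_ratio")]) == 1))
  b2 <- transform(b, qt_interval = 140, t_amplitude = -8)
  r2 <- ratio_of_change(b, b2)
  expect_equal(r2$qt_interval_ratio, 0.5)
  expect_equal(r2$t_amplitude_ratio, 2)
  expect_equal(r2$substituted, "")
})

test_that("degenerate control denominators fall back to differences", {
  b <- tibble::tibble(qrs_duration = 20, qt_interval = 280, st_deviation = 0,
                      t_duration = 35, qrs_amplitude = 18, t_amplitude = -4)
  b2 <- transform(b, st_deviation = -0.3)
  r <- ratio_of_change(b, b2)
  expect_equal(r$st_deviation_ratio, -0.3) # difference, not ratio
  expect_match(r$substituted, "st_deviation")
})
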