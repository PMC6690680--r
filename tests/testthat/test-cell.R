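test_that("the resting baseline state is near equilibrium", {
  d <- tp06_rhs(stimulus = 0)
  expect_lt(abs(d$dstate[["v"]]), 0.1)
})

test_that("f_inhib scales I_Na and I_CaL linearly at a fixed state", {
  # evaluate at a depolarised state where both currents are active
  st <- tp06_state()
  st["v"] <- -20
  st["m"] <- 0.9; st["h"] <- 0.3; st["j"] <- 0.3
  st["d"] <- 0.5; st["f"] <- 0.7
  r1 <- tp06_rhs(st, spec = ischemia_spec("control"))
  r2 <- tp06_rhs(st, spec = ischemia_spec(f_katp = 0, f_inhib = 0.75, ko = 5.4))
  expect_equal(r2$currents$i_na / r1$currents$i_na, 0.75, tolerance = 1e-12)
  expect_equal(r2$currents$i_cal / r1$currents$i_cal, 0.75, tolerance = 1e-12)
})

test_that("conductance scaling is linear per channel at a fixed state", {
  st <- tp06_state()
  st["v"] <- -20
  st["m"] <- 0.9; st["h"] <- 0.3; st["j"] <- 0.3
  st["xr1"] <- 0.5; st["xs"] <- 0.3; st["r"] <- 0.4
  base <- tp06_rhs(st)$currents
  for (chan in list(c("g_na", "i_na"), c("g_kr", "i_kr"), c("g_ks", "i_ks"),
                    c("g_to", "i_to"), c("p_nak", "i_nak"),
                    c("k_naca", "i_naca"))) {
    sc <- baseline_scaling()
    sc[chan[1]] <- 2
    doubled <- tp06_rhs(st, scaling = sc)$currents
    expect_equal(doubled[[chan[2]]] / base[[chan[2]]], 2, tolerance = 1e-12,
                 label = chan[1])
  }
})

test_that("pacing is deterministic: identical inputs give identical traces", {
  p <- pacing_protocol(cl = 430, n_beats = 3)
  t1 <- pace_cell(protocol = p)
  t2 <- pace_cell(protocol = p)
  expect_identical(t1$v, t2$v)
  expect_identical(t1$time, t2$time)
})

test_that("a zero-amplitude stimulus elicits no action potential", {
  tr <- pace_cell(protocol = pacing_protocol(cl = 600, n_beats = 2,
                                             stim_amplitude = 0))
  expect_lt(max(tr$v), 0)
  b <- ap_biomarkers(tr)
  expect_lt(b$apa, 0)
  expect_true(is.na(b$apd90))
})

test_that("ischemic severity orders APD, RMP and APA on the baseline model", {
  bio <- lapply(c("control", "mild", "severe"), function(sev) {
    ap_biomarkers(pace_cell(spec = ischemia_spec(sev),
                            protocol = pacing_protocol(cl = 600, n_beats = 100)))
  })
  apd <- sapply(bio, `[[`, "apd90")
  rmp <- sapply(bio, `[[`, "rmp")
  apa <- sapply(bio, `[[`, "apa")
  expect_true(apd[1] > apd[2] && apd[2] > apd[3]) # APD shortens
  expect_true(rmp[1] < rmp[2] && rmp[2] < rmp[3]) # RMP depolarises
  expect_gt(apa[1], apa[3])                       # amplitude falls
})

test_that("hyperkalemia raises the resting potential without pacing", {
  relax <- function(spec) {
    tr <- pace_cell(spec = spec,
                    protocol = pacing_protocol(cl = 2000, n_beats = 2,
                                               stim_amplitude = 0))
    tail(tr$v, 1)
  }
  expect_gt(relax(ischemia_spec("severe")), relax(ischemia_spec("control")))
})

test_that("invalid pacing and scaling inputs are rejected", {
  expect_error(pacing_protocol(cl = 0.5, stim_duration = 1),
               class = "pecgsim_invalid_parameter")
  expect_error(pacing_protocol(n_beats = 0), class = "pecgsim_invalid_parameter")
  sc <- baseline_scaling()
  sc["g_na"] <- 2.5
  expect_error(pace_cell(sc), class = "pecgsim_invalid_parameter")
  expect_error(tp06_rhs(spec = ischemia_spec(f_katp = 0, f_inhib = 1, ko = -2)),
               class = "pecgsim_invalid_parameter")
})

test_that("the fast stepper agrees with the stiff reference integrator", {
  proto <- pacing_protocol(cl = 600, n_beats = 2)
  fast <- pace_cell(protocol = proto)
  ref <- pace_cell_reference(protocol = proto)
  b_fast <- ap_biomarkers(fast)
  b_ref <- ap_biomarkers(ref)
  expect_equal(b_fast$apd90, b_ref$apd90, tolerance = 0.02)
  # the sharp upstroke peak carries the largest discretisation error of the
  # 0.02 ms forward-Euler step (refining the step converges onto the
  # reference value); durations and resting potential are tight
  expect_equal(b_fast$apa, b_ref$apa, tolerance = 0.07)
  expect_equal(b_fast$rmp, b_ref$rmp, tolerance = 0.005)
  fine <- pace_cell(protocol = proto,
                    solver = solver_settings(dt_fast = 0.005, dt_slow = 0.1,
                                             record_dt = 0.1))
  expect_equal(ap_biomarkers(fine)$apa, b_ref$apa, tolerance = 0.02)
})
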