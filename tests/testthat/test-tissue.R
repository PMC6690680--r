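test_that("regional ischemia profiles follow the piecewise-linear geometry", {
  sev <- ischemia_spec("severe")
  prof <- region_profile(sev, zone_size = 0.5)
  # zone [0.75, 1.25] at preset; transitions [0.65, 0.75] and [1.25, 1.35]
  at <- function(xq) prof[which.min(abs(prof$x - xq)), ]
  expect_equal(at(1.0)$ko, 9.0)
  expect_equal(at(0.76)$ko, 9.0)
  expect_equal(at(0.5)$ko, 5.4)
  expect_equal(at(1.5)$f_katp, 0)
  # mid-transition node at x = 0.70: exactly midway
  expect_equal(at(0.70)$ko, (5.4 + 9.0) / 2, tolerance = 1e-9)
  expect_equal(at(0.70)$f_inhib, (1 + 0.75) / 2, tolerance = 1e-9)
  expect_equal(at(0.70)$f_katp, 0.1, tolerance = 1e-9)
})

test_that("a 2 cm zone makes the whole cable ischemic", {
  prof <- region_profile(ischemia_spec("mild"), zone_size = 2)
  expect_true(all(prof$ko == 6.25))
  expect_true(all(prof$f_inhib == 0.875))
})

test_that("non-positive zone sizes are rejected", {
  expect_error(region_profile(ischemia_spec("mild"), zone_size = 0),
               class = "pecgsim_invalid_parameter")
})

test_that("activation times increase along the cable at a ~60 cm/s scale", {
  sol <- short_cable()
  at <- apply(sol$v, 2, function(vv) sol$time[which(vv > 0)[1]])
  expect_true(all(diff(at) >= 0))
  cv <- conduction_velocity(sol)$cv
  expect_gt(cv, 40)
  expect_lt(cv, 90)
})

test_that("decoupled cells do not propagate", {
  g <- cable_geometry(length = 0.4, diffusivity = 0)
  sol <- simulate_cable(geometry = g, profile = control_profile(g),
                        protocol = pacing_protocol(cl = 400, n_beats = 1))
  expect_gt(max(sol$v[, 1]), 0)        # stimulated node fires
  expect_lt(max(sol$v[, 15]), -60)     # distal node never depolarises
})

test_that("a uniform unstimulated field stays spatially uniform", {
  g <- cable_geometry(length = 0.4)
  sol <- simulate_cable(geometry = g, profile = control_profile(g),
                        protocol = pacing_protocol(cl = 200, n_beats = 1,
                                                   stim_amplitude = 0))
  spread <- apply(sol$v, 1, function(r) diff(range(r)))
  expect_true(all(spread < 1e-9))
})

test_that("whole-cable activation keeps a symmetric profile mirror-symmetric", {
  # stimulate every node simultaneously: the discrete operator is symmetric
  # about the cable midpoint, so the field must stay mirror-symmetric
  g <- cable_geometry(length = 1)
  prof <- region_profile(ischemia_spec("severe"), zone_size = 0.4, geometry = g)
  sol <- simulate_cable(profile = prof, geometry = g,
                        protocol = pacing_protocol(cl = 300, n_beats = 1),
                        stim_nodes = g$n_nodes)
  asym <- max(abs(sol$v - sol$v[, rev(seq_len(ncol(sol$v)))]))
  expect_lt(asym, 1e-8)
})

test_that("refining the spatial grid changes baseline CV by less than 5%", {
  cv_at <- function(dx) {
    g <- cable_geometry(dx = dx)
    # explicit diffusion needs dt <= dx^2/(2 D): keep the fine step only
    sol <- simulate_cable(geometry = g, profile = control_profile(g),
                          protocol = pacing_protocol(cl = 600, n_beats = 2),
                          stim_nodes = round(0.06 / dx), # fixed 0.06 cm footprint
                          solver = solver_settings(dt_slow = 0.02,
                                                   record_dt = 0.1))
    conduction_velocity(sol)$cv
  }
  expect_lt(abs(cv_at(0.01) - cv_at(0.02)) / cv_at(0.02), 0.05)
})

test_that("the cable stepper agrees with the stiff reference on a short fiber", {
  g <- cable_geometry(length = 1)
  proto <- pacing_protocol(cl = 500, n_beats = 1)
  # refined-step operator splitting converges onto the stiff method-of-lines
  # reference; the production step (0.02 ms) trades a small CV underestimate
  # for speed (conduction converges from below as the step is refined)
  fine <- simulate_cable(geometry = g, profile = control_profile(g),
                         protocol = proto,
                         solver = solver_settings(dt_fast = 0.005,
                                                  dt_slow = 0.02,
                                                  record_dt = 0.02))
  ref <- simulate_cable_reference(geometry = g, profile = control_profile(g),
                                  protocol = proto, record_dt = 0.02)
  cv_fine <- conduction_velocity(fine, l1 = 0.2, l2 = 0.8)$cv
  cv_r <- conduction_velocity(ref, l1 = 0.2, l2 = 0.8)$cv
  expect_equal(cv_fine, cv_r, tolerance = 0.02)
  prod <- simulate_cable(geometry = g, profile = control_profile(g),
                         protocol = proto,
                         solver = solver_settings(dt_slow = 0.02,
                                                  record_dt = 0.02))
  cv_p <- conduction_velocity(prod, l1 = 0.2, l2 = 0.8)$cv
  expect_equal(cv_p, cv_r, tolerance = 0.05)
})

test_that("severity ordering of conduction velocity on the baseline model", {
  proto <- pacing_protocol(cl = 600, n_beats = 5)
  cvs <- sapply(c("control", "mild", "severe"), function(sev) {
    prof <- if (sev == "control") control_profile() else
      region_profile(ischemia_spec(sev), zone_size = 2)
    conduction_velocity(simulate_cable(profile = prof, protocol = proto))$cv
  })
  expect_gte(cvs["control"], cvs["mild"])
  expect_gt(cvs["mild"], cvs["severe"])
})
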