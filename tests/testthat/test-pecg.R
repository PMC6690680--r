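make_solution <- function(vfun, geometry = cable_geometry(),
                          times = seq(0, 10, by = 0.5)) {
  structure(list(time = times,
                 v = outer(times, geometry$x, vfun),
                 x = geometry$x, geometry = geometry,
                 profile = control_profile(geometry), cl = 600),
            class = "cable_solution")
}

test_that("a spatially uniform field produces a null pseudo-ECG", {
  sol <- make_solution(function(t, x) -85 + 0 * x + t)
  phi <- compute_pecg(sol)$phi
  expect_true(all(abs(phi) < 1e-10))
})

test_that("a static linear ramp matches the closed-form integral", {
  # V(l) = l  =>  -dV/dl = -1; Phi_e = -A * int_a^b (4 - l)^-2 dl
  #             = -A * [1/(4 - l)]_a^b with a = 0.3, b = 1.7 (cells 15..85)
  sol <- make_solution(function(t, x) x + 0 * t)
  phi <- compute_pecg(sol)$phi
  expected <- -(1 / (4 - 1.7) - 1 / (4 - 0.3))
  # trapezoid truncation at dx = 0.02 is O(dx^2) ~ 3e-5 relative
  expect_equal(phi[1], expected, tolerance = 5e-5)
  # high-resolution quadrature matches the antiderivative to 6 digits
  g2 <- cable_geometry(dx = 0.002)
  sol2 <- make_solution(function(t, x) x + 0 * t, geometry = g2)
  phi2 <- compute_pecg(sol2, probe_config(window = 150:850))$phi
  expect_equal(phi2[1], expected, tolerance = 1e-6)
})

test_that("the pseudo-ECG is linear in the voltage field and in A", {
  f1 <- function(t, x) sin(x) * (1 + t)
  f2 <- function(t, x) x^2 - 3 * x
  s1 <- make_solution(f1)
  s2 <- make_solution(f2)
  s12 <- make_solution(function(t, x) f1(t, x) + f2(t, x))
  expect_equal(compute_pecg(s12)$phi,
               compute_pecg(s1)$phi + compute_pecg(s2)$phi, tolerance = 1e-12)
  pr <- probe_config(amplitude = 3.5)
  expect_equal(compute_pecg(s1, pr)$phi, 3.5 * compute_pecg(s1)$phi,
               tolerance = 1e-12)
})

test_that("quadrature error decreases like the square of the node spacing", {
  # smooth analytic field; compare against a very fine discretisation
  f <- function(t, x) exp(-x) * (1 + 0 * t)
  phi_at <- function(dx, frac = c(0.15, 0.85)) {
    g <- cable_geometry(dx = dx)
    w <- seq(round(frac[1] * (g$n_nodes - 1)), round(frac[2] * (g$n_nodes - 1)))
    compute_pecg(make_solution(f, g), probe_config(window = w))$phi[1]
  }
  ref <- phi_at(0.0025)
  e1 <- abs(phi_at(0.02) - ref)
  e2 <- abs(phi_at(0.01) - ref)
  expect_lt(e2, e1 / 3) # ~4x reduction expected for O(dx^2)
})

test_that("a probe inside the cable is rejected", {
  sol <- make_solution(function(t, x) x)
  expect_error(compute_pecg(sol, probe_config(position = 1)),
               class = "pecgsim_invalid_parameter")
})

test_that("the control cable yields a positive QRS and near-isoelectric ST", {
  pecg <- compute_pecg(short_cable())
  d <- delineate_pecg(pecg)
  expect_gt(d$qrs_amplitude, 0)
  # ST level is small relative to the QRS deflection
  expect_lt(abs(d$st_deviation), 0.05 * d$qrs_amplitude)
  # the depolarisation wave travels toward the probe: early deflection upward
  expect_gt(max(pecg$phi[pecg$time < 50]), 0)
})
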