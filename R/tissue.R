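#' 1D cable geometry
#'
#' A homogeneous strand of ventricular myocytes: length 2 cm, inter-cell
#' spacing 0.02 cm (101 nodes), cell-to-cell diffusivity
#' `1.171e-3` cm^2/ms. The diffusivity is expressed per millisecond — the
#' value that reproduces conduction velocities on the 60 cm/s scale for the
#' baseline model (see the methods vignette for the unit discussion).
#'
#' @param length cable length, cm.
#' @param dx node spacing, cm.
#' @param diffusivity cell-to-cell coupling, cm^2/ms.
#' @return An object of class `cable_geometry` with fields `length`, `dx`,
#'   `diffusivity`, `n_nodes` and node positions `x` (cm).
#' @examples
#' cable_geometry()
#' @export
cable_geometry <- function(length = 2, dx = 0.02, diffusivity = 1.171e-3) {
  n <- round(length / dx) + 1
  structure(list(length = length, dx = dx, diffusivity = diffusivity,
                 n_nodes = as.integer(n), x = seq(0, length, by = dx)),
            class = "cable_geometry")
}

#' Per-node ischemia profile for a regionally ischemic cable
#'
#' Defines an ischemic region of size `zone_size` centred at the cable
#' midpoint, flanked by transition regions of length `transition` on each
#' side in which `f_katp`, `f_inhib` and `ko` ramp linearly between the
#' ischemic preset and control. Nodes outside zone and transitions carry
#' control values. Transitions are truncated at the cable ends, so the
#' largest zone (2 cm) makes the entire cable fully ischemic.
#'
#' @param spec an [ischemia_spec()] (the preset inside the zone).
#' @param zone_size size of the central ischemic region, cm.
#' @param geometry a [cable_geometry()].
#' @param transition transition length on each side, cm.
#' @return A tibble with one row per node: `node` (1-based index), `x` (cm),
#'   `f_katp`, `f_inhib`, `ko`, plus the severity label and zone size as
#'   attributes.
#' @examples
#' prof <- region_profile(ischemia_spec("severe"), zone_size = 1)
#' dplyr::count(prof, f_katp)
#' @export
region_profile <- function(spec, zone_size, geometry = cable_geometry(),
                           transition = 0.1) {
  stopifnot(inherits(spec, "ischemia_spec"), inherits(geometry, "cable_geometry"))
  if (zone_size <= 0) {
    abort("zone_size must be positive", class = "pecgsim_invalid_parameter")
  }
  ctrl <- ischemia_spec("control")
  x <- geometry$x
  mid <- geometry$length / 2
  z0 <- mid - zone_size / 2
  z1 <- mid + zone_size / 2
  # weight: 1 inside the zone, linear in transitions, 0 outside (clamped at
  # cable ends so a full-length zone is fully ischemic)
  w <- numeric(length(x))
  w[x >= z0 & x <= z1] <- 1
  lo <- x < z0
  w[lo] <- pmax(0, 1 - (z0 - x[lo]) / transition)
  hi <- x > z1
  w[hi] <- pmax(0, 1 - (x[hi] - z1) / transition)
  out <- tibble(
    node = seq_along(x), x = x,
    f_katp = ctrl$f_katp + w * (spec$f_katp - ctrl$f_katp),
    f_inhib = ctrl$f_inhib + w * (spec$f_inhib - ctrl$f_inhib),
    ko = ctrl$ko + w * (spec$ko - ctrl$ko)
  )
  attr(out, "severity") <- spec$severity
  attr(out, "zone_size") <- zone_size
  out
}

#' Control (uniform) cable profile
#'
#' @inheritParams region_profile
#' @return A per-node profile with control values everywhere.
#' @export
control_profile <- function(geometry = cable_geometry()) {
  out <- region_profile(ischemia_spec("mild"), zone_size = geometry$dx / 2,
                        geometry = geometry, transition = geometry$dx / 4)
  out$f_katp <- 0
  out$f_inhib <- 1
  out$ko <- 5.4
  attr(out, "severity") <- "control"
  attr(out, "zone_size") <- 0
  out
}

#' Simulate action-potential propagation along a 1D cable
#'
#' Solves the monodomain reaction-diffusion equation
#' \deqn{\partial V/\partial t = D \, \partial^2 V/\partial x^2 - I_{ion}}
#' by the method of lines: second-order central differences in space with
#' no-flux (Neumann) boundaries, and the same dual-step operator-splitting
#' integrator as [pace_cell()]. The cable is homogeneous in its conductance
#' scaling; ischemia may vary per node through `profile`. Stimulation is
#' applied to the first `stim_nodes` nodes at `x = 0`; 30 beats are paced by
#' default and the final beat is recorded every 0.5 ms.
#'
#' @inheritParams pace_cell
#' @param profile per-node ischemia tibble from [region_profile()] /
#'   [control_profile()].
#' @param geometry a [cable_geometry()].
#' @param protocol a [pacing_protocol()]; defaults to 30 beats at 600 ms.
#' @param stim_nodes number of stimulated nodes at the `x = 0` end.
#' @param record_dt output sampling of the saved beat, ms.
#' @param state0 either `NULL` (published resting state at every node), a
#'   single named state vector to replicate (warm start from a single-cell
#'   steady state), or a full `19 x n_nodes` matrix.
#' @return A `cable_solution`: list with `time` (ms), `v` (matrix, time by
#'   node, mV), `x` (node positions, cm), `profile`, `geometry`, `cl` and
#'   the protocol.
#' @examples
#' \donttest{
#' sol <- simulate_cable(protocol = pacing_protocol(cl = 600, n_beats = 5))
#' conduction_velocity(sol)
#' }
#' @export
simulate_cable <- function(scaling = baseline_scaling(),
                           profile = control_profile(),
                           geometry = cable_geometry(),
                           protocol = pacing_protocol(cl = 600, n_beats = 30),
                           stim_nodes = 3,
                           solver = solver_settings(record_dt = 0.5),
                           record_dt = NULL,
                           state0 = NULL) {
  sc <- check_scaling(scaling)
  stopifnot(inherits(geometry, "cable_geometry"))
  if (nrow(profile) != geometry$n_nodes) {
    abort("profile must have one row per cable node",
          class = "pecgsim_invalid_parameter")
  }
  if (!is.null(record_dt)) solver$record_dt <- record_dt
  nn <- geometry$n_nodes
  if (is.null(state0)) state0 <- tp06_state()
  if (is.null(dim(state0))) state0 <- matrix(rep(unname(state0), nn), nrow = 19)
  res <- .tp06_cable_cpp(sc, profile$f_katp, profile$f_inhib, profile$ko,
                         geometry$diffusivity, geometry$dx,
                         protocol$cl, protocol$n_beats,
                         protocol$stim_amplitude, protocol$stim_duration,
                         as.integer(stim_nodes),
                         solver$dt_fast, solver$dt_slow, solver$record_dt,
                         solver$dvdt_switch, state0)
  structure(list(time = res$time, v = res$v, x = geometry$x,
                 profile = profile, geometry = geometry, cl = protocol$cl,
                 protocol = protocol, state_final = res$state_final),
            class = "cable_solution")
}

#' Reference cable integration with a stiff adaptive solver
#'
#' Method-of-lines solution of the cable equation with
#' [deSolve::lsoda()] and a banded Jacobian, at the same tolerances as the
#' single-cell reference. Used to validate the production stepper on short
#' runs; it is orders of magnitude slower.
#'
#' @inheritParams simulate_cable
#' @param rtol,atol solver tolerances.
#' @return A `cable_solution`.
#' @export
simulate_cable_reference <- function(scaling = baseline_scaling(),
                                     profile = control_profile(),
                                     geometry = cable_geometry(),
                                     protocol = pacing_protocol(cl = 600, n_beats = 2),
                                     stim_nodes = 3,
                                     record_dt = 0.5,
                                     state0 = NULL,
                                     rtol = 1e-3, atol = 1e-6) {
  sc <- check_scaling(scaling)
  nn <- geometry$n_nodes
  if (is.null(state0)) state0 <- tp06_state()
  if (is.null(dim(state0))) state0 <- matrix(rep(unname(state0), nn), nrow = 19)
  rD <- geometry$diffusivity / geometry$dx^2
  fk <- profile$f_katp; fi <- profile$f_inhib; ko <- profile$ko
  deriv <- function(t, y, parms) {
    S <- matrix(y, nrow = 19)
    tb <- t %% protocol$cl
    stim <- tb < protocol$stim_duration
    D <- matrix(0, 19, nn)
    for (j in seq_len(nn)) {
      istim <- if (stim && j <= stim_nodes) protocol$stim_amplitude else 0
      D[, j] <- .tp06_derivs_cpp(S[, j], sc, fk[j], fi[j], ko[j], istim)$dstate
    }
    vv <- S[1, ]
    lap <- rD * (c(vv[2], vv[-nn]) - 2 * vv + c(vv[-1], vv[nn - 1]))
    D[1, ] <- D[1, ] + lap
    list(as.vector(D))
  }
  times <- seq(0, protocol$cl * protocol$n_beats, by = record_dt)
  sol <- deSolve::lsoda(as.vector(state0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol,
                        jactype = "bandint", bandup = 19, banddown = 19,
                        maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) {
    abort("stiff reference solver failed", class = "pecgsim_numerical_failure")
  }
  last <- times >= protocol$cl * (protocol$n_beats - 1)
  vidx <- 1 + seq(1, by = 19, length.out = nn)
  structure(list(time = times[last] - protocol$cl * (protocol$n_beats - 1),
                 v = unname(sol[last, vidx, drop = FALSE]),
                 x = geometry$x, profile = profile, geometry = geometry,
                 cl = protocol$cl, protocol = protocol),
            class = "cable_solution")
}

#' @export
print.cable_solution <- function(x, ...) {
  cat(sprintf(
    "<cable_solution> %d nodes x %d samples, CL %g ms, severity %s (zone %g cm)\n",
    length(x$x), length(x$time), x$cl,
    attr(x$profile, "severity") %||% "?", attr(x$profile, "zone_size") %||% NA))
  invisible(x)
}

#' Tidy a cable solution into long format
#'
#' @param x a `cable_solution`.
#' @param ... unused.
#' @return Tibble with columns `time` (ms), `x` (cm), `v` (mV).
#' @export
tidy.cable_solution <- function(x, ...) {
  tibble(time = rep(x$time, times = length(x$x)),
         x = rep(x$x, each = length(x$time)),
         v = as.vector(x$v))
}

#' Conduction velocity along a cable
#'
#' \deqn{CV = (l_2 - l_1) / (AT(l_2) - AT(l_1))}
#' where the activation time \eqn{AT(l)} is the first instant the membrane
#' potential at `l` surpasses zero. Positions default to 0.4 and 1.6 cm.
#'
#' @param solution a `cable_solution`.
#' @param l1,l2 measurement positions, cm.
#' @return One-row tibble: `cv` (cm/s), `at_l1`, `at_l2` (ms), `l1`, `l2`.
#' @export
conduction_velocity <- function(solution, l1 = 0.4, l2 = 1.6) {
  stopifnot(inherits(solution, "cable_solution"))
  at <- function(l) {
    j <- which.min(abs(solution$x - l))
    i <- which(solution$v[, j] > 0)[1]
    if (is.na(i)) {
      abort(sprintf("no activation at l = %g cm (conduction block)", l),
            class = "pecgsim_propagation_failure")
    }
    solution$time[i]
  }
  t1 <- at(l1); t2 <- at(l2)
  if (t2 <= t1) {
    abort("activation times not increasing between the measurement points",
          class = "pecgsim_propagation_failure")
  }
  tibble(cv = (l2 - l1) / (t2 - t1) * 1000, at_l1 = t1, at_l2 = t2,
         l1 = l1, l2 = l2)
}
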