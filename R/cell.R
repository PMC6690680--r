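#' Names of the sampled maximal conductances and peak currents
#'
#' The population axis of variability: every maximal conductance / peak
#' current of the TP06 ventricular myocyte model receives a dimensionless
#' multiplier in `[0, 2]`. The twelve targets are the sodium conductance
#' (`g_na`), L-type calcium (`g_cal`), rapid and slow delayed rectifiers
#' (`g_kr`, `g_ks`), inward rectifier (`g_k1`), transient outward (`g_to`),
#' plateau potassium and calcium (`g_pk`, `g_pca`), background sodium and
#' calcium (`g_bna`, `g_bca`), the sodium-potassium pump (`p_nak`) and the
#' sodium-calcium exchanger (`k_naca`).
#'
#' @return Character vector of length 12.
#' @examples
#' tp06_factors()
#' @export
tp06_factors <- function() {
  c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to", "g_pk", "g_pca",
    "g_bna", "g_bca", "p_nak", "k_naca")
}

#' Baseline (all-ones) scaling factors
#'
#' @return Named numeric vector of 1s over [tp06_factors()]; applying it
#'   reproduces the published TP06 epicardial baseline.
#' @examples
#' baseline_scaling()
#' @export
baseline_scaling <- function() {
  setNames(rep(1, 12), tp06_factors())
}

check_scaling <- function(scaling) {
  if (is.data.frame(scaling)) scaling <- unlist(scaling[1, tp06_factors()])
  if (!is.null(names(scaling))) {
    missing <- setdiff(tp06_factors(), names(scaling))
    if (length(missing) > 0) {
      abort(paste("scaling is missing factors:", paste(missing, collapse = ", ")),
            class = "pecgsim_invalid_parameter")
    }
    scaling <- scaling[tp06_factors()]
  }
  if (length(scaling) != 12 || !is.numeric(scaling)) {
    abort("scaling must be a numeric vector over the 12 TP06 factors",
          class = "pecgsim_invalid_parameter")
  }
  if (any(scaling < 0) || any(scaling > 2)) {
    abort("scale factors must lie in [0, 2]", class = "pecgsim_invalid_parameter")
  }
  unname(scaling)
}

#' Initial state of the TP06 model
#'
#' @return Named numeric vector of the 19 state variables (membrane
#'   potential `v` in mV, intracellular concentrations in mM, gates
#'   dimensionless) at the published resting values.
#' @examples
#' tp06_state()
#' @export
tp06_state <- function() {
  .tp06_initial_state_cpp()
}

#' Pacing protocol
#'
#' @param cl cycle length, ms.
#' @param n_beats number of paced beats; only the final beat is recorded
#'   unless `record_all = TRUE`.
#' @param stim_amplitude stimulus current, A/F (negative = depolarising).
#' @param stim_duration stimulus duration, ms.
#' @param record_all record the membrane potential of every beat instead of
#'   only the last one.
#' @return An object of class `pacing_protocol`.
#' @examples
#' pacing_protocol(cl = 600, n_beats = 200)
#' @export
pacing_protocol <- function(cl = 600, n_beats = 200, stim_amplitude = -52,
                            stim_duration = 1, record_all = FALSE) {
  if (n_beats < 1) abort("n_beats must be >= 1", class = "pecgsim_invalid_parameter")
  if (!(cl > stim_duration && stim_duration > 0)) {
    abort("need CL > stimulus duration > 0", class = "pecgsim_invalid_parameter")
  }
  structure(list(cl = cl, n_beats = as.integer(n_beats),
                 stim_amplitude = stim_amplitude, stim_duration = stim_duration,
                 record_all = isTRUE(record_all)),
            class = "pacing_protocol")
}

#' Time-stepping settings for the operator-splitting solver
#'
#' The production integrator uses Rush-Larsen updates for the
#' Hodgkin-Huxley gates and forward Euler for the membrane potential and
#' concentrations, alternating between a fine step during fast
#' depolarisation (when |dV/dt| exceeds `dvdt_switch`) and a coarser step
#' elsewhere. Steps are integer-aligned so that identical inputs give
#' bit-identical traces.
#'
#' @param dt_fast fine time step, ms.
#' @param dt_slow coarse time step, ms; must be an integer multiple of
#'   `dt_fast`.
#' @param record_dt output sampling interval, ms; must be an integer
#'   multiple of `dt_slow`.
#' @param dvdt_switch |dV/dt| threshold (mV/ms) above which the fine step
#'   is used.
#' @return An object of class `solver_settings`.
#' @examples
#' solver_settings()
#' @export
solver_settings <- function(dt_fast = 0.02, dt_slow = 0.1, record_dt = 0.1,
                            dvdt_switch = 1) {
  ks <- dt_slow / dt_fast
  kr <- record_dt / dt_slow
  if (abs(ks - round(ks)) > 1e-9 || abs(kr - round(kr)) > 1e-9) {
    abort("dt_slow must be a multiple of dt_fast and record_dt of dt_slow",
          class = "pecgsim_invalid_parameter")
  }
  structure(list(dt_fast = dt_fast, dt_slow = dt_slow, record_dt = record_dt,
                 dvdt_switch = dvdt_switch),
            class = "solver_settings")
}

spec_or_default <- function(spec) {
  if (is.null(spec)) ischemia_spec("control") else spec
}

#' Evaluate the TP06 right-hand side with ischemia overlay
#'
#' Computes the time derivative of the full 19-variable state together with
#' the individual membrane currents. The ischemia overlay adds
#' \eqn{I_{K(ATP)}} (see [ikatp_current()]), multiplies \eqn{I_{Na}} and
#' \eqn{I_{CaL}} by `f_inhib`, and uses `ko` in every potassium-dependent
#' reversal potential and current.
#'
#' @param state named numeric state vector, see [tp06_state()].
#' @param scaling named numeric vector of conductance multipliers over
#'   [tp06_factors()] (or a one-row data frame with those columns).
#' @param spec an [ischemia_spec()].
#' @param stimulus applied stimulus current, A/F.
#' @return A list with `dstate` (named derivative vector, per ms) and
#'   `currents`, a one-row tibble of the thirteen membrane currents (A/F)
#'   and the four reversal potentials (mV).
#' @examples
#' tp06_rhs(stimulus = 0)$currents
#' @export
tp06_rhs <- function(state = tp06_state(), scaling = baseline_scaling(),
                     spec = ischemia_spec("control"), stimulus = 0) {
  sc <- check_scaling(scaling)
  stopifnot(inherits(spec, "ischemia_spec"))
  out <- .tp06_derivs_cpp(unname(state), sc, spec$f_katp, spec$f_inhib,
                          spec$ko, stimulus)
  names(out$dstate) <- names(tp06_state())
  out$currents <- as_tibble(as.list(out$currents))
  out
}

new_ap_trace <- function(time, v, cl, protocol, spec, beat_apd, converged) {
  out <- tibble(time = time, v = v)
  class(out) <- c("ap_trace", class(out))
  attr(out, "cl") <- cl
  attr(out, "protocol") <- protocol
  attr(out, "spec") <- spec
  attr(out, "beat_apd") <- beat_apd
  attr(out, "converged") <- converged
  out
}

#' Pace a single myocyte to steady state
#'
#' Integrates the TP06 model under the given pacing protocol and returns the
#' saved beat as an action-potential trace sampled on a uniform grid
#' (default 0.1 ms). Steady-state pacing uses 200 beats by default; only the
#' final beat is kept unless the protocol requests all beats.
#'
#' Beat-to-beat convergence is monitored with a per-beat duration proxy;
#' if it still fluctuates by more than 1 ms across the last five beats the
#' trace is flagged (`attr(trace, "converged") == FALSE`) but not rejected.
#'
#' @inheritParams tp06_rhs
#' @param protocol a [pacing_protocol()].
#' @param state0 initial state vector (defaults to the published resting
#'   state).
#' @param solver a [solver_settings()].
#' @return An `ap_trace`: a tibble with columns `time` (ms, covering one
#'   cycle of the saved beat) and `v` (mV), carrying the cycle length,
#'   protocol, ischemia spec and convergence flag as attributes.
#' @examples
#' \donttest{
#' tr <- pace_cell(protocol = pacing_protocol(cl = 600, n_beats = 20))
#' ap_biomarkers(tr)
#' }
#' @export
pace_cell <- function(scaling = baseline_scaling(),
                      spec = ischemia_spec("control"),
                      protocol = pacing_protocol(),
                      state0 = tp06_state(),
                      solver = solver_settings()) {
  sc <- check_scaling(scaling)
  stopifnot(inherits(spec, "ischemia_spec"), inherits(protocol, "pacing_protocol"))
  res <- .tp06_pace_cpp(sc, spec$f_katp, spec$f_inhib, spec$ko,
                        protocol$cl, protocol$n_beats,
                        protocol$stim_amplitude, protocol$stim_duration,
                        solver$dt_fast, solver$dt_slow, solver$record_dt,
                        solver$dvdt_switch, unname(state0), protocol$record_all)
  ba <- res$beat_apd
  converged <- if (length(ba) >= 5) {
    max(abs(diff(tail(ba, 5)))) <= 1
  } else TRUE
  tr <- new_ap_trace(res$time, res$v, protocol$cl, protocol, spec, ba, converged)
  attr(tr, "state_final") <- res$state_final
  tr
}

#' Reference single-cell integration with a stiff adaptive solver
#'
#' Integrates the same right-hand side as [pace_cell()] with
#' [deSolve::lsoda()] at relative tolerance `1e-3` and absolute tolerance
#' `1e-6`. This is the validation route for the production
#' operator-splitting stepper; it is considerably slower and intended for
#' short runs.
#'
#' @inheritParams pace_cell
#' @param rtol,atol relative / absolute solver tolerances.
#' @return An `ap_trace` for the final beat, sampled every
#'   `solver$record_dt` ms.
#' @export
pace_cell_reference <- function(scaling = baseline_scaling(),
                                spec = ischemia_spec("control"),
                                protocol = pacing_protocol(n_beats = 2),
                                state0 = tp06_state(),
                                solver = solver_settings(),
                                rtol = 1e-3, atol = 1e-6) {
  sc <- check_scaling(scaling)
  deriv <- function(t, y, parms) {
    tb <- t %% protocol$cl
    stim <- if (tb < protocol$stim_duration) protocol$stim_amplitude else 0
    list(.tp06_derivs_cpp(y, sc, spec$f_katp, spec$f_inhib, spec$ko, stim)$dstate)
  }
  times <- seq(0, protocol$cl * protocol$n_beats, by = solver$record_dt)
  sol <- deSolve::lsoda(unname(state0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    abort("stiff reference solver failed", class = "pecgsim_numerical_failure")
  }
  last <- times >= protocol$cl * (protocol$n_beats - 1)
  new_ap_trace(times[last] - protocol$cl * (protocol$n_beats - 1),
               sol[last, 2], protocol$cl, protocol, spec,
               beat_apd = numeric(0), converged = NA)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> CL %g ms, %d samples, peak %0.1f mV%s\n",
              attr(x, "cl"), nrow(x), max(x$v),
              if (isFALSE(attr(x, "converged"))) " [non-converged]" else ""))
  NextMethod()
}
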