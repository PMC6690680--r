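#' Virtual probe configuration for pseudo-ECG synthesis
#'
#' The unipolar probe sits on the fiber axis 2 cm beyond the cable end
#' (position 4 cm for the default 2 cm cable). Only cells 15 to 85
#' (0-based node indices from the stimulated end) enter the integral, which
#' keeps stimulus and sealed-end artifacts out of the signal. The amplitude
#' constant is 1: the pseudo-ECG scale is arbitrary and cancels in ratio
#' features.
#'
#' @param position probe position, cm (must lie outside the cable).
#' @param window integration window as 0-based node indices.
#' @param amplitude multiplicative constant A.
#' @return Object of class `probe_config`.
#' @examples
#' probe_config()
#' @export
probe_config <- function(position = 4, window = 15:85, amplitude = 1) {
  structure(list(position = position, window = as.integer(window),
                 amplitude = amplitude),
            class = "probe_config")
}

#' Pseudo-ECG at a virtual unipolar probe
#'
#' Computes the extracellular potential
#' \deqn{\Phi_e(l') = A \int (-\partial V/\partial l)\,
#'   \frac{\partial}{\partial l}\Big(\frac{1}{|l - l'|}\Big)\, dl}
#' over the probe's node window, per time sample of the cable solution. The
#' spatial gradient uses central differences and the integral the
#' trapezoidal rule. In 1D the kernel is
#' \eqn{\mathrm{sign}(l'-l)/(l-l')^2}, so a depolarisation wave propagating
#' toward the probe produces a positive deflection.
#'
#' @param solution a `cable_solution` from [simulate_cable()].
#' @param probe a [probe_config()].
#' @return A `pecg_trace`: tibble with columns `time` (ms) and `phi`
#'   (arbitrary units), carrying severity/zone provenance attributes.
#' @examples
#' \donttest{
#' sol <- simulate_cable(protocol = pacing_protocol(cl = 600, n_beats = 5))
#' pecg <- compute_pecg(sol)
#' delineate_pecg(pecg)
#' }
#' @export
compute_pecg <- function(solution, probe = probe_config()) {
  stopifnot(inherits(solution, "cable_solution"), inherits(probe, "probe_config"))
  x <- solution$x
  lp <- probe$position
  if (lp >= min(x) && lp <= max(x)) {
    abort("probe must lie outside the cable (singular kernel)",
          class = "pecgsim_invalid_parameter")
  }
  nodes <- probe$window + 1L # 0-based cells -> 1-based node indices
  if (any(nodes < 2L) || any(nodes > length(x) - 1L)) {
    abort("integration window must be strictly inside the cable",
          class = "pecgsim_invalid_parameter")
  }
  v <- solution$v
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  dx <- solution$geometry$dx
  # central-difference spatial gradient at interior nodes
  grad <- (v[, nodes + 1L, drop = FALSE] -
             v[, nodes - 1L, drop = FALSE]) / (2 * dx)
  kern <- sign(lp - x[nodes]) / (x[nodes] - lp)^2
  integrand <- sweep(-grad, 2, kern, `*`)
  w <- rep(dx, length(nodes))
  w[1] <- w[length(w)] <- dx / 2 # trapezoid
  phi <- probe$amplitude * as.vector(integrand %*% w)
  out <- tibble(time = solution$time, phi = phi)
  class(out) <- c("pecg_trace", class(out))
  attr(out, "severity") <- attr(solution$profile, "severity")
  attr(out, "zone_size") <- attr(solution$profile, "zone_size")
  attr(out, "cl") <- solution$cl
  out
}

#' @export
print.pecg_trace <- function(x, ...) {
  cat(sprintf("<pecg_trace> %d samples, severity %s, peak %0.3g\n",
              nrow(x), attr(x, "severity") %||% "?", max(abs(x$phi))))
  NextMethod()
}
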