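#' Acute-ischemia parameter specification
#'
#' Acute myocardial ischemia is represented by three superimposed cellular
#' effects: hypoxia, modelled by an ATP-sensitive potassium current
#' \eqn{I_{K(ATP)}} scaled by `f_katp`; acidosis, modelled by a constant
#' multiplicative inhibition `f_inhib` of the fast sodium current
#' \eqn{I_{Na}} and the L-type calcium current \eqn{I_{CaL}}; and
#' hyperkalemia, modelled by raising the extracellular potassium
#' concentration `ko` above its 5.4 mM control value.
#'
#' The named severity presets are: control `(0, 1, 5.4)`, mild
#' `(0.1, 0.875, 6.25)` and severe `(0.2, 0.75, 9.0)`; mild sits at the
#' mid-point between no ischemia and the severe stage.
#'
#' @param severity one of `"control"`, `"mild"`, `"severe"`, or `"custom"`
#'   when the three parameters are supplied explicitly.
#' @param f_katp dimensionless scaling of the ATP-sensitive potassium
#'   conductance (0 = no hypoxic effect).
#' @param f_inhib dimensionless multiplier applied to \eqn{I_{Na}} and
#'   \eqn{I_{CaL}} (1 = no acidotic inhibition).
#' @param ko extracellular potassium concentration, mM.
#' @return An object of class `ischemia_spec`: a list with fields `severity`,
#'   `f_katp`, `f_inhib`, `ko`, plus the constants `ko_n = 5.4` mM and
#'   `g_katp = 0.064` mS/uF.
#' @examples
#' ischemia_spec("severe")
#' ischemia_spec(f_katp = 0.05, f_inhib = 0.95, ko = 5.8)
#' @export
ischemia_spec <- function(severity = c("control", "mild", "severe", "custom"),
                          f_katp = NULL, f_inhib = NULL, ko = NULL) {
  explicit <- !is.null(f_katp) || !is.null(f_inhib) || !is.null(ko)
  severity <- if (explicit && missing(severity)) "custom" else match.arg(severity)
  preset <- switch(severity,
    control = c(0, 1, 5.4),
    mild = c(0.1, 0.875, 6.25),
    severe = c(0.2, 0.75, 9.0),
    custom = c(NA_real_, NA_real_, NA_real_)
  )
  f_katp <- f_katp %||% preset[1]
  f_inhib <- f_inhib %||% preset[2]
  ko <- ko %||% preset[3]
  if (anyNA(c(f_katp, f_inhib, ko))) {
    abort("a custom ischemia_spec needs f_katp, f_inhib and ko",
          class = "pecgsim_invalid_parameter")
  }
  if (!is.numeric(ko) || length(ko) != 1 || ko <= 0) {
    abort("extracellular potassium `ko` must be a positive scalar (mM)",
          class = "pecgsim_invalid_parameter")
  }
  if (f_katp < 0 || f_inhib < 0 || f_inhib > 1) {
    abort("need f_katp >= 0 and f_inhib in [0, 1]",
          class = "pecgsim_invalid_parameter")
  }
  structure(
    list(severity = severity, f_katp = f_katp, f_inhib = f_inhib, ko = ko,
         ko_n = 5.4, g_katp = 0.064),
    class = "ischemia_spec"
  )
}

#' @export
print.ischemia_spec <- function(x, ...) {
  cat("<ischemia_spec> ", x$severity,
      sprintf(": f_katp = %g, f_inhib = %g, [K+]o = %g mM\n",
              x$f_katp, x$f_inhib, x$ko))
  invisible(x)
}

#' Severity presets for acute ischemia
#'
#' @return A tibble with one row per severity stage (`control`, `mild`,
#'   `severe`) and columns `f_katp`, `f_inhib`, `ko`.
#' @examples
#' ischemia_presets()
#' @export
ischemia_presets <- function() {
  tibble(
    severity = c("control", "mild", "severe"),
    f_katp = c(0, 0.1, 0.2),
    f_inhib = c(1, 0.875, 0.75),
    ko = c(5.4, 6.25, 9.0)
  )
}

#' ATP-sensitive potassium current
#'
#' Evaluates the hypoxia current
#' \deqn{I_{K(ATP)} = f_{K(ATP)} \, G_{K(ATP)} \,
#'   ([K^+]_o / [K^+]_{o,n})^{0.24} \, (V - E_K)}
#' with \eqn{G_{K(ATP)} = 0.064} mS/uF and \eqn{[K^+]_{o,n} = 5.4} mM.
#'
#' @param spec an [ischemia_spec()].
#' @param v membrane potential, mV (vectorised).
#' @param ek potassium reversal potential, mV (vectorised).
#' @return Current density in A/F, same length as `v`.
#' @examples
#' sp <- ischemia_spec("severe")
#' ikatp_current(sp, v = -50, ek = nernst_k(sp$ko))
#' @export
ikatp_current <- function(spec, v, ek) {
  stopifnot(inherits(spec, "ischemia_spec"))
  if (spec$ko <= 0) {
    abort("extracellular potassium must be positive",
          class = "pecgsim_invalid_parameter")
  }
  spec$f_katp * spec$g_katp * (spec$ko / spec$ko_n)^0.24 * (v - ek)
}

#' Nernst potential for potassium at 310 K
#'
#' @param ko extracellular potassium, mM.
#' @param ki intracellular potassium, mM (TP06 initial value by default).
#' @return Reversal potential in mV.
#' @examples
#' nernst_k(5.4)
#' nernst_k(9.0, ki = 138)
#' @export
nernst_k <- function(ko, ki = 138.3) {
  if (any(ko <= 0) || any(ki <= 0)) {
    abort("concentrations must be positive", class = "pecgsim_invalid_parameter")
  }
  (8314.472 * 310 / 96485.3415) * log(ko / ki)
}
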