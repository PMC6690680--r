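#' Plot an action-potential trace
#'
#' @param object an `ap_trace` from [pace_cell()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  title = sprintf("Action potential, CL %g ms", attr(object, "cl"))) +
    ggplot2::theme_minimal()
}

#' Plot a pseudo-ECG trace, optionally with its delineation landmarks
#'
#' @param object a `pecg_trace` from [compute_pecg()].
#' @param delineate draw the QRS/T onset and end landmarks.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pecg_trace <- function(object, delineate = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = expression(Phi[e] ~ "(a.u.)"),
                  title = sprintf("Pseudo-ECG (%s)", attr(object, "severity") %||% "")) +
    ggplot2::theme_minimal()
  if (delineate) {
    d <- delineate_pecg(object)
    marks <- tibble(t = c(d$qrs_onset, d$qrs_end, d$t_onset, d$t_end),
                    what = c("QRS on", "QRS end", "T on", "T end"))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$t),
                                 linetype = 3, colour = "grey40")
  }
  p
}

#' Space-time map of a cable solution
#'
#' @param object a `cable_solution`.
#' @param ... unused.
#' @return A ggplot raster of V(t, x).
#' @export
autoplot.cable_solution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$x, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "V (mV)") +
    ggplot2::labs(x = "time (ms)", y = "position (cm)") +
    ggplot2::theme_minimal()
}

#' Biomarker distributions of a population
#'
#' @param object an `epom_population`.
#' @param ... unused.
#' @return A ggplot of the accepted models' biomarker histograms.
#' @export
autoplot.epom_population <- function(object, ...) {
  cls <- attr(object, "cls") %||% c(430, 600)
  cols <- c(paste0("apd90_", cls), "apa", "rmp")
  acc <- dplyr::filter(as_tibble(object), .data$accepted)
  long <- tidyr::pivot_longer(acc[cols], dplyr::everything(),
                              names_to = "biomarker")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~biomarker, scales = "free") +
    ggplot2::labs(x = NULL, y = "models") +
    ggplot2::theme_minimal()
}

#' Biomarkers as a function of the ischemic-region size
#'
#' @param sweep tibble from [zone_sweep()].
#' @param features which biomarkers to draw.
#' @param ratio draw ratio-of-change features instead of magnitudes.
#' @return A ggplot, one facet per biomarker.
#' @export
plot_zone_sweep <- function(sweep, features = pecg_feature_names(),
                            ratio = FALSE) {
  cols <- if (ratio) paste0(features, "_ratio") else features
  long <- tidyr::pivot_longer(sweep[c("severity", "zone_size", cols)],
                              dplyr::all_of(cols), names_to = "biomarker")
  ggplot2::ggplot(dplyr::filter(long, .data$severity != "control"),
                  ggplot2::aes(.data$zone_size, .data$value,
                               colour = .data$severity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~biomarker, scales = "free_y") +
    ggplot2::labs(x = "ischemic region size (cm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
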