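#' Action-potential biomarkers
#'
#' Extracts the four single-cell biomarkers from a one-beat trace:
#'
#' * `apa` — action potential amplitude: peak membrane potential, measured
#'   with respect to zero (mV);
#' * `rmp` — resting membrane potential: the potential at the end of the
#'   cycle (mV);
#' * `upstroke_time` — time from stimulus onset to peak potential (ms);
#' * `apd90` — action potential duration: time from activation (the instant
#'   of maximal dV/dt) until repolarisation reaches 10% of the APA
#'   (`apd_method = "apa10"`, the default); with `apd_method = "repol90"`
#'   the conventional 90%-repolarisation-toward-RMP level is used instead.
#'
#' The default APD convention follows the source formulation in which the
#' amplitude is referenced to zero; it is the convention under which the
#' baseline model satisfies the monophasic-APD calibration ranges (see the
#' methods vignette for the comparison of the two conventions).
#'
#' @param trace an `ap_trace` from [pace_cell()], or any data frame with
#'   `time` and `v` columns covering a single beat.
#' @param stim_time stimulus onset within the trace, ms.
#' @param apd_method `"apa10"` (repolarisation to 10% of APA w.r.t. zero) or
#'   `"repol90"` (90% repolarisation toward RMP).
#' @param upstroke_method `"stim_to_peak"` (default) or `"rise_10_90"`
#'   (10-90% rise time of the upstroke).
#' @return A one-row tibble with columns `apd90`, `apa`, `rmp`,
#'   `upstroke_time`. When no action potential is elicited (peak below
#'   0 mV), `apd90` is `NA` and the remaining biomarkers are still reported.
#' @examples
#' \donttest{
#' tr <- pace_cell(protocol = pacing_protocol(n_beats = 20))
#' ap_biomarkers(tr)
#' }
#' @export
ap_biomarkers <- function(trace, stim_time = 0,
                          apd_method = c("apa10", "repol90"),
                          upstroke_method = c("stim_to_peak", "rise_10_90")) {
  apd_method <- match.arg(apd_method)
  upstroke_method <- match.arg(upstroke_method)
  tt <- trace$time
  v <- trace$v
  if (length(tt) < 3 || is.unsorted(tt, strictly = TRUE)) {
    abort("trace must have a strictly increasing time grid",
          class = "pecgsim_invalid_parameter")
  }
  ipk <- which.max(v)
  apa <- v[ipk]
  rmp <- v[length(v)]
  upstroke <- if (upstroke_method == "stim_to_peak") {
    tt[ipk] - stim_time
  } else {
    lo <- rmp + 0.1 * (apa - rmp)
    hi <- rmp + 0.9 * (apa - rmp)
    i10 <- which(v >= lo)[1]
    i90 <- which(v >= hi)[1]
    if (is.na(i10) || is.na(i90)) NA_real_ else
      cross_time(tt, v, i90, hi, backward = FALSE) -
      cross_time(tt, v, i10, lo, backward = FALSE)
  }

  apd <- NA_real_
  if (apa > 0) {
    dvdt <- diff(v) / diff(tt)
    act <- tt[which.max(dvdt)]
    level <- if (apd_method == "apa10") 0.1 * apa else apa - 0.9 * (apa - rmp)
    below <- which(tt > tt[ipk] & v < level)
    if (length(below) > 0) {
      apd <- cross_time(tt, v, below[1], level, backward = FALSE) - act
    }
  }
  tibble(apd90 = apd, apa = apa, rmp = rmp, upstroke_time = upstroke)
}

# linear interpolation of the crossing time at index i (v crosses `level`
# between samples i-1 and i)
cross_time <- function(tt, v, i, level, backward = FALSE) {
  if (i == 1) return(tt[1])
  f <- (level - v[i - 1]) / (v[i] - v[i - 1])
  f <- min(max(f, 0), 1)
  tt[i - 1] + f * (tt[i] - tt[i - 1])
}

#' Monophasic APD calibration ranges
#'
#' Experimental monophasic action potential duration ranges from healthy
#' human ventricle, used to calibrate the control population at the two
#' pacing rates.
#'
#' @return Tibble with columns `cl` (ms), `lower`, `upper` (ms).
#' @examples
#' calibration_ranges()
#' @export
calibration_ranges <- function() {
  tibble(cl = c(430, 600), lower = c(170, 195), upper = c(240, 290))
}

#' Physiological exclusion of a paced model
#'
#' A candidate model is excluded when its action potential lies outside what
#' is considered healthy: amplitude below 0 mV, resting membrane potential
#' above -64 mV, or upstroke time exceeding 10 ms. The first failed
#' criterion (in that order) is reported as the rejection reason.
#'
#' @param bio one-row tibble from [ap_biomarkers()].
#' @return A list with `accepted` (logical) and `reason` (`NA`, `"apa"`,
#'   `"rmp"` or `"upstroke"`).
#' @examples
#' exclude_model(tibble::tibble(apd90 = 220, apa = 52, rmp = -85,
#'                              upstroke_time = 2))
#' @export
exclude_model <- function(bio) {
  if (bio$apa < 0) return(list(accepted = FALSE, reason = "apa"))
  if (bio$rmp > -64) return(list(accepted = FALSE, reason = "rmp"))
  if (is.na(bio$upstroke_time) || bio$upstroke_time > 10) {
    return(list(accepted = FALSE, reason = "upstroke"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' APD calibration of a paced model
#'
#' A model is kept only when its APD90 lies inside the closed experimental
#' range at every calibration cycle length.
#'
#' @param apd90 named numeric vector of APD90 values (ms), one per cycle
#'   length, with names equal to the cycle length (e.g.
#'   `c("430" = 200, "600" = 250)`).
#' @param ranges tibble as returned by [calibration_ranges()].
#' @return Logical: `TRUE` when all cycle lengths are in range.
#' @examples
#' calibrate_model(c("430" = 220, "600" = 250))
#' @export
calibrate_model <- function(apd90, ranges = calibration_ranges()) {
  have <- as.numeric(names(apd90))
  if (!all(ranges$cl %in% have)) {
    abort("apd90 must provide a value for every calibration cycle length",
          class = "pecgsim_invalid_parameter")
  }
  ok <- vapply(seq_len(nrow(ranges)), function(i) {
    a <- apd90[[as.character(ranges$cl[i])]]
    !is.na(a) && a >= ranges$lower[i] && a <= ranges$upper[i]
  }, logical(1))
  all(ok)
}
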