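#' Delineate a pseudo-ECG beat into its six biomarkers
#'
#' Identifies the QRS complex (the major deflection within `qrs_window` ms
#' of the stimulus) and the T wave (the last major deflection before cycle
#' end), then measures:
#'
#' * `qrs_duration` — QRS offset minus onset, ms;
#' * `qt_interval` — T-wave end minus QRS onset, ms;
#' * `st_deviation` — signal amplitude at the midpoint between QRS end and
#'   T-wave onset (signal units, signed);
#' * `t_duration` — T-wave end minus onset, ms;
#' * `qrs_amplitude` — maximum signal value during the QRS complex;
#' * `t_amplitude` — signal value at the T-wave peak (signed; the peak is
#'   located on |phi| so inverted or biphasic T waves are handled).
#'
#' Wave onsets and ends are the instants where |phi| crosses 10% of the
#' wave's peak magnitude on the corresponding flank (linearly interpolated
#' between samples). Brief sub-threshold gaps shorter than `gap` ms within a
#' complex (notched or biphasic morphologies) do not terminate the wave.
#'
#' @param trace a `pecg_trace` (or data frame with `time`, `phi`), one beat.
#' @param qrs_window time window after stimulus onset searched for the QRS
#'   complex, ms.
#' @param threshold flank threshold as a fraction of the reference peak.
#' @param t_reference reference peak for the T-wave flank threshold:
#'   `"qrs"` (default) uses 10% of the QRS peak magnitude, which separates
#'   the T deflection proper from the shallow repolarisation-dispersion
#'   ramp that precedes it on these fiber signals; `"wave"` uses 10% of the
#'   T wave's own peak. The QRS-referenced variant reproduces the reported
#'   population T-duration and QT scales (see the methods vignette).
#' @param gap sub-threshold gap tolerated inside a wave, ms; also the
#'   minimal separation enforced between QRS end and T-wave search.
#' @return One-row tibble with the six biomarkers plus the delineation
#'   landmarks `qrs_onset`, `qrs_end`, `t_onset`, `t_end` (ms).
#' @examples
#' tt <- seq(0, 400, by = 0.5)
#' tri <- function(t, t0, t1, pk) pmax(0, 1 - abs(t - (t0 + t1) / 2) /
#'                                          ((t1 - t0) / 2)) * pk
#' trace <- tibble::tibble(time = tt, phi = tri(tt, 10, 40, 1) +
#'                                          tri(tt, 200, 260, 0.5))
#' delineate_pecg(trace)
#' @export
delineate_pecg <- function(trace, qrs_window = 150, threshold = 0.1,
                           t_reference = c("qrs", "wave"), gap = 10) {
  t_reference <- match.arg(t_reference)
  tt <- trace$time
  phi <- trace$phi
  if (all(abs(phi) < .Machine$double.eps * 100)) {
    abort("no waves found in the pseudo-ECG (flat trace)",
          class = "pecgsim_delineation_error")
  }
  a <- abs(phi)
  dt <- stats::median(diff(tt))
  gap_n <- max(1L, ceiling(gap / dt))

  in_qrs <- which(tt <= tt[1] + qrs_window)
  pq <- in_qrs[which.max(a[in_qrs])]
  qrs <- wave_bounds(tt, a, pq, threshold * a[pq], gap_n,
                     lo = 1L, hi = max(in_qrs))
  # T wave: last major deflection after the QRS complex
  after <- which(tt > qrs$t_end + gap)
  if (length(after) < 3) {
    abort("no samples left after the QRS complex to search for a T wave",
          class = "pecgsim_delineation_error")
  }
  pt <- after[which.max(a[after])]
  if (a[pt] < .Machine$double.eps * 100) {
    abort("no distinguishable T wave after the QRS complex",
          class = "pecgsim_delineation_error")
  }
  t_thr <- threshold * if (t_reference == "qrs") a[pq] else a[pt]
  if (a[pt] <= t_thr) {
    abort("T deflection does not rise above the flank threshold",
          class = "pecgsim_delineation_error")
  }
  tw <- wave_bounds(tt, a, pt, t_thr, gap_n,
                    lo = min(after), hi = length(tt))

  st_mid <- (qrs$t_end + tw$t_onset) / 2
  st <- approx(tt, phi, xout = st_mid, rule = 2)$y
  qrs_idx <- tt >= qrs$t_onset & tt <= qrs$t_end
  tibble(
    qrs_duration = qrs$t_end - qrs$t_onset,
    qt_interval = tw$t_end - qrs$t_onset,
    st_deviation = st,
    t_duration = tw$t_end - tw$t_onset,
    qrs_amplitude = max(phi[qrs_idx]),
    t_amplitude = phi[pt],
    qrs_onset = qrs$t_onset, qrs_end = qrs$t_end,
    t_onset = tw$t_onset, t_end = tw$t_end
  )
}

# flank crossings of |phi| at `thr` around peak index p, tolerating
# sub-threshold gaps shorter than gap_n samples within [lo, hi]:
# above-threshold runs separated by short gaps are merged into one wave
wave_bounds <- function(tt, a, p, thr, gap_n, lo, hi) {
  idx <- lo:hi
  above <- a[idx] >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(list(t_onset = tt[p], t_end = tt[p]))
  # merge runs separated by gaps shorter than gap_n samples
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - merged$end[nrow(merged)] - 1 < gap_n) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  prel <- p - lo + 1
  w <- which(merged$start <= prel & merged$end >= prel)[1]
  if (is.na(w)) w <- which.min(pmin(abs(merged$start - prel),
                                    abs(merged$end - prel)))
  i0 <- merged$start[w] + lo - 1 # first above-threshold sample
  i1 <- merged$end[w] + lo - 1   # last above-threshold sample
  onset <- if (i0 > lo) {
    f <- (thr - a[i0 - 1]) / (a[i0] - a[i0 - 1])
    tt[i0 - 1] + f * (tt[i0] - tt[i0 - 1])
  } else tt[lo]
  t_end <- if (i1 < hi) {
    f <- (a[i1] - thr) / (a[i1] - a[i1 + 1])
    tt[i1] + f * (tt[i1 + 1] - tt[i1])
  } else tt[hi]
  list(t_onset = onset, t_end = t_end)
}

#' Ratio of change of pseudo-ECG biomarkers
#'
#' For each of the six biomarkers, the ratio \eqn{b' = b_I / b_C} of the
#' ischemic value to the same model's control value. When the control value
#' is numerically degenerate (|b_C| below `floor_frac` times the control QRS
#' amplitude — the ST deviation of a healthy cable is essentially zero), the
#' ratio is replaced by the signed difference \eqn{b_I - b_C} and the
#' substitution is recorded.
#'
#' @param control,ischemic one-row tibbles from [delineate_pecg()] for the
#'   same underlying model.
#' @param floor_frac degeneracy floor as a fraction of the control QRS
#'   amplitude.
#' @return One-row tibble with columns `<biomarker>_ratio` and a
#'   `substituted` character column naming biomarkers (comma-separated)
#'   whose ratio was replaced by a difference.
#' @examples
#' b <- tibble::tibble(qrs_duration = 20, qt_interval = 280, st_deviation = 0,
#'                     t_duration = 35, qrs_amplitude = 18, t_amplitude = -4)
#' ratio_of_change(b, b)
#' @export
ratio_of_change <- function(control, ischemic, floor_frac = 1e-6) {
  feats <- pecg_feature_names()
  floor_abs <- floor_frac * abs(control$qrs_amplitude)
  subs <- character(0)
  vals <- lapply(feats, function(f) {
    bc <- control[[f]]
    bi <- ischemic[[f]]
    if (abs(bc) <= floor_abs) {
      subs <<- c(subs, f)
      bi - bc
    } else {
      bi / bc
    }
  })
  out <- as_tibble(setNames(vals, paste0(feats, "_ratio")))
  out$substituted <- paste(subs, collapse = ",")
  out
}

#' Names of the six pseudo-ECG biomarkers
#'
#' @return Character vector in the conventional order.
#' @export
pecg_feature_names <- function() {
  c("qrs_duration", "qt_interval", "st_deviation", "t_duration",
    "qrs_amplitude", "t_amplitude")
}
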