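# shared fixtures, computed lazily once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# baseline model paced to steady state at the two calibration rates
baseline_trace <- function(cl) {
  fixture(paste0("trace_", cl), pace_cell(
    protocol = pacing_protocol(cl = cl, n_beats = 200)))
}

# short baseline control cable (5 beats: enough for propagation/pECG shape)
short_cable <- function() {
  fixture("short_cable", simulate_cable(
    protocol = pacing_protocol(cl = 600, n_beats = 5)))
}

# triangular two-wave synthetic pseudo-ECG (QRS peak 1 over [10, 40] ms,
# T peak 0.5 over [200, 260] ms), 0.5 ms grid
triangle_pecg <- function(qrs_pk = 1, t_pk = 0.5, dt = 0.5) {
  tri <- function(t, t0, t1, pk) {
    m <- (t0 + t1) / 2
    pmax(0, 1 - abs(t - m) / (m - t0)) * pk
  }
  tt <- seq(0, 400, by = dt)
  tibble::tibble(time = tt,
                 phi = tri(tt, 10, 40, qrs_pk) + tri(tt, 200, 260, t_pk))
}

# tiny linearly-separable two-class dataset (well-separated Gaussian pair)
separable_dataset <- function(n = 40, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, mean = -2, sd = 0.3), ncol = 2),
             matrix(rnorm(n * 2, mean = 2, sd = 0.3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("neg", "pos"), each = n)
  ml_dataset(x, y, n_folds = 5, seed = seed)
}
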