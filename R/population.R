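#' Latin hypercube sample of conductance scaling factors
#'
#' Draws `n` scaling-factor combinations in `[0, 2]^d` by Latin hypercube
#' sampling: each one-dimensional marginal places exactly one sample in each
#' of the `n` equal-width strata `[2k/n, 2(k+1)/n)`.
#'
#' @param n number of parameter combinations.
#' @param seed integer seed; the same seed reproduces the same design.
#' @param factors names of the sampled parameters (defaults to the twelve
#'   TP06 targets).
#' @return A tibble with `n` rows, an `id` column and one column per factor.
#' @examples
#' sample_scaling(4, seed = 1, factors = c("g_na", "g_kr"))
#' @export
sample_scaling <- function(n, seed = 1, factors = tp06_factors()) {
  if (n < 1) abort("n must be >= 1", class = "pecgsim_invalid_parameter")
  set.seed(seed)
  design <- 2 * lhs::randomLHS(n, length(factors))
  colnames(design) <- factors
  dplyr::bind_cols(tibble(id = seq_len(n)), as_tibble(design))
}

#' Build an experimentally-calibrated population of models (ePoM)
#'
#' Runs the full control-population procedure: Latin hypercube sampling of
#' the twelve conductance multipliers in `[0, 2]`, steady-state pacing of
#' every candidate at each calibration cycle length (430 and 600 ms, 200
#' beats), physiological exclusion (APA < 0, RMP > -64 mV, upstroke > 10 ms)
#' and APD90 calibration against the monophasic ranges at both rates.
#'
#' Candidates are processed in sample order (results are independent of any
#' parallel scheduling) and every rejection records its first failed
#' criterion; solver failures are recorded as reason `"numerical"`. To save
#' work, a candidate rejected at the first cycle length is not paced at the
#' second; its unmeasured biomarkers are `NA`.
#'
#' @inheritParams sample_scaling
#' @param n_samples number of Latin hypercube samples.
#' @param cls calibration cycle lengths, ms.
#' @param n_beats pre-pacing beats per cycle length.
#' @param ranges calibration ranges, see [calibration_ranges()].
#' @param solver a [solver_settings()].
#' @param apd_method APD convention passed to [ap_biomarkers()].
#' @param keep_states keep the final model state at the last cycle length as
#'   a list-column (`state`), enabling warm-started cable runs.
#' @param progress print a line every `progress` candidates (0 = silent).
#' @return An `epom_population`: a tibble with one row per candidate (id,
#'   the twelve factors, `apd90_<cl>` per cycle length, `apa`, `rmp`,
#'   `upstroke_time` measured at the largest cycle length, `accepted`,
#'   `reason`, optionally `state`), with the acceptance fraction, seed,
#'   ranges and protocol stored as attributes.
#' @examples
#' \donttest{
#' pop <- build_population(20, seed = 42, n_beats = 50)
#' attr(pop, "acceptance_fraction")
#' }
#' @export
build_population <- function(n_samples, seed = 1, cls = c(430, 600),
                             n_beats = 200, ranges = calibration_ranges(),
                             solver = solver_settings(),
                             apd_method = "apa10",
                             keep_states = TRUE, progress = 0) {
  samples <- sample_scaling(n_samples, seed = seed)
  cls <- sort(cls)
  report_cl <- max(cls)
  control <- ischemia_spec("control")

  rows <- vector("list", n_samples)
  states <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sc <- unlist(samples[i, tp06_factors()])
    apd <- setNames(rep(NA_real_, length(cls)), cls)
    bio_report <- NULL
    accepted <- TRUE
    reason <- NA_character_
    for (cl in cls) {
      tr <- tryCatch(
        pace_cell(sc, control, pacing_protocol(cl = cl, n_beats = n_beats),
                  solver = solver),
        error = function(e) e
      )
      if (inherits(tr, "error")) {
        accepted <- FALSE
        reason <- "numerical"
        break
      }
      bio <- ap_biomarkers(tr, apd_method = apd_method)
      apd[as.character(cl)] <- bio$apd90
      # biomarkers of the last cycle length reached (the reporting CL for
      # accepted models, the rejecting CL otherwise)
      bio_report <- bio
      if (cl == report_cl) states[[i]] <- attr(tr, "state_final")
      ex <- exclude_model(bio)
      if (!ex$accepted) {
        accepted <- FALSE
        reason <- ex$reason
        break
      }
      r <- ranges[ranges$cl == cl, ]
      if (nrow(r) == 1 &&
          (is.na(bio$apd90) || bio$apd90 < r$lower || bio$apd90 > r$upper)) {
        accepted <- FALSE
        reason <- paste0("apd_", cl)
        break
      }
    }
    rows[[i]] <- tibble(
      apa = if (is.null(bio_report)) NA_real_ else bio_report$apa,
      rmp = if (is.null(bio_report)) NA_real_ else bio_report$rmp,
      upstroke_time = if (is.null(bio_report)) NA_real_ else bio_report$upstroke_time,
      accepted = accepted, reason = reason,
      !!!setNames(as.list(apd), paste0("apd90_", names(apd)))
    )
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("processed %d / %d candidates", i, n_samples))
    }
  }

  out <- dplyr::bind_cols(samples, dplyr::bind_rows(rows))
  if (keep_states) out$state <- states
  class(out) <- c("epom_population", class(out))
  attr(out, "acceptance_fraction") <- mean(out$accepted)
  attr(out, "seed") <- seed
  attr(out, "ranges") <- ranges
  attr(out, "cls") <- cls
  attr(out, "n_beats") <- n_beats
  attr(out, "apd_method") <- apd_method
  out
}

#' @export
print.epom_population <- function(x, ...) {
  cat(sprintf("<epom_population> %d candidates, %d accepted (%.1f%%), seed %s\n",
              nrow(x), sum(x$accepted), 100 * mean(x$accepted),
              format(attr(x, "seed"))))
  NextMethod()
}

#' Summarise the biomarkers of an accepted population
#'
#' @param population an `epom_population` from [build_population()].
#' @return Tibble with one row per biomarker (`mean`, `sd`, `n`) over the
#'   accepted models, mirroring the usual population-of-models report.
#' @export
population_summary <- function(population) {
  acc <- dplyr::filter(population, .data$accepted)
  cls <- attr(population, "cls") %||% c(430, 600)
  cols <- c(paste0("apd90_", max(cls)), "apa", "rmp", "upstroke_time")
  tidyr::pivot_longer(acc[cols], dplyr::everything(),
                      names_to = "biomarker") |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Persist / restore a population as plain-text artifacts
#'
#' Writes the population index as CSV (one row per candidate; list-column
#' states are written to a companion CSV of stacked state vectors).
#'
#' @param population an `epom_population`.
#' @param path output CSV path; the states file (if present) gets suffix
#'   `_states.csv`.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  idx <- dplyr::select(population, -dplyr::any_of("state"))
  write.csv(idx, path, row.names = FALSE)
  if (!is.null(population$state)) {
    st <- population$state
    keep <- !vapply(st, is.null, logical(1))
    if (any(keep)) {
      m <- do.call(rbind, st[keep])
      sdf <- data.frame(id = population$id[keep], m, check.names = FALSE)
      write.csv(sdf, sub("\\.csv$", "_states.csv", path), row.names = FALSE)
    }
  }
  invisible(path)
}
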