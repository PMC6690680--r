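#' Pseudo-ECG feature rows for one model under all severities
#'
#' Runs the control cable and one fully-ischemic (2 cm zone by default)
#' cable per ischemic severity for a single parameter set, synthesises the
#' pseudo-ECGs, delineates them, and returns one feature row per severity:
#' the six biomarker magnitudes, the six ratios of change with respect to
#' the model's own control cable (control rows carry ratios of exactly 1),
#' and the conduction velocity.
#'
#' @inheritParams simulate_cable
#' @param id model identifier carried into the output.
#' @param severities character vector of ischemic severities to simulate in
#'   addition to control.
#' @param zone_size ischemic-region size, cm.
#' @param probe a [probe_config()].
#' @param warm_state optional single-cell steady state (named vector) used
#'   to warm-start every node, e.g. the `state` column of
#'   [build_population()]; `NULL` starts from the published resting state.
#' @return Tibble with one row per severity: `id`, `severity`, `zone_size`,
#'   `cv`, the six magnitudes and the six `_ratio` features.
#' @export
model_features <- function(scaling, id = NA_integer_,
                           severities = c("mild", "severe"),
                           zone_size = 2,
                           geometry = cable_geometry(),
                           protocol = pacing_protocol(cl = 600, n_beats = 30),
                           probe = probe_config(),
                           solver = solver_settings(record_dt = 0.5),
                           warm_state = NULL) {
  run_one <- function(profile) {
    sol <- simulate_cable(scaling, profile, geometry, protocol,
                          solver = solver, state0 = warm_state)
    list(delin = delineate_pecg(compute_pecg(sol, probe)),
         cv = conduction_velocity(sol)$cv)
  }
  ctrl <- run_one(control_profile(geometry))
  feats <- pecg_feature_names()
  rows <- list(dplyr::bind_cols(
    tibble(id = id, severity = "control", zone_size = 0, cv = ctrl$cv),
    ctrl$delin[feats],
    ratio_of_change(ctrl$delin, ctrl$delin)
  ))
  for (sev in severities) {
    prof <- region_profile(ischemia_spec(sev), zone_size, geometry)
    res <- run_one(prof)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(id = id, severity = sev, zone_size = zone_size, cv = res$cv),
      res$delin[feats],
      ratio_of_change(ctrl$delin, res$delin)
    )
  }
  dplyr::bind_rows(rows)
}

#' Build the classifier feature table from an accepted population
#'
#' Applies [model_features()] to every accepted model of a population (or
#' the first `n_models` of them), yielding the machine-learning substrate:
#' one labelled example per (model, severity).
#'
#' Models whose cable blocks (no propagated beat, typically under severe
#' ischemia with a weak sodium current) or whose pseudo-ECG cannot be
#' delineated are skipped; their ids and failure messages are kept in the
#' `"failed_models"` attribute of the result. Accepted models are consumed
#' in population order until `n_models` usable models are collected (or the
#' population is exhausted).
#'
#' @param population an `epom_population` from [build_population()].
#' @param n_models number of usable accepted models to collect.
#' @param warm_start warm-start cable nodes from each model's single-cell
#'   steady state (requires `keep_states = TRUE` upstream).
#' @param progress print a line every `progress` models (0 = silent).
#' @inheritParams model_features
#' @return Feature tibble, one row per (model, severity).
#' @export
feature_table <- function(population, n_models = Inf,
                          severities = c("mild", "severe"), zone_size = 2,
                          protocol = pacing_protocol(cl = 600, n_beats = 30),
                          warm_start = FALSE, progress = 0, ...) {
  acc <- dplyr::filter(population, .data$accepted)
  if (nrow(acc) == 0) {
    abort("population has no accepted models", class = "pecgsim_invalid_parameter")
  }
  rows <- list()
  failed <- list()
  for (i in seq_len(nrow(acc))) {
    if (length(rows) >= n_models) break
    sc <- unlist(acc[i, tp06_factors()])
    ws <- if (warm_start && !is.null(acc$state)) acc$state[[i]] else NULL
    res <- tryCatch(
      model_features(sc, id = acc$id[i], severities = severities,
                     zone_size = zone_size, protocol = protocol,
                     warm_state = ws, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <- tibble(id = acc$id[i],
                                             message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("features: %d models done, %d usable, %d failed",
                      i, length(rows), length(failed)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failed_models") <- dplyr::bind_rows(failed)
  out
}

#' Sweep the ischemic-region size for one model
#'
#' @inheritParams model_features
#' @param zones ischemic-region sizes, cm.
#' @return Tibble with one row per (severity, zone size) plus a control row,
#'   containing the six magnitudes, ratios and CV.
#' @export
zone_sweep <- function(scaling = baseline_scaling(),
                       severities = c("mild", "severe"),
                       zones = c(0.5, 1, 1.5, 2),
                       geometry = cable_geometry(),
                       protocol = pacing_protocol(cl = 600, n_beats = 30),
                       probe = probe_config(),
                       solver = solver_settings(record_dt = 0.5),
                       warm_state = NULL) {
  ctrl_sol <- simulate_cable(scaling, control_profile(geometry), geometry,
                             protocol, solver = solver, state0 = warm_state)
  ctrl <- delineate_pecg(compute_pecg(ctrl_sol, probe))
  feats <- pecg_feature_names()
  rows <- list(dplyr::bind_cols(
    tibble(severity = "control", zone_size = 0,
           cv = conduction_velocity(ctrl_sol)$cv),
    ctrl[feats], ratio_of_change(ctrl, ctrl)
  ))
  for (sev in severities) {
    for (z in zones) {
      sol <- simulate_cable(scaling,
                            region_profile(ischemia_spec(sev), z, geometry),
                            geometry, protocol, solver = solver,
                            state0 = warm_state)
      d <- delineate_pecg(compute_pecg(sol, probe))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(severity = sev, zone_size = z,
               cv = conduction_velocity(sol)$cv),
        d[feats], ratio_of_change(ctrl, d)
      )
    }
  }
  dplyr::bind_rows(rows)
}

ratio_feature_names <- function() paste0(pecg_feature_names(), "_ratio")

#' Train the ischemia classifiers on a feature table
#'
#' Reproduces the two learning structures:
#'
#' * `ann1` — a single multi-class perceptron mapping the six biomarker
#'   magnitudes to one-hot (control, mild, severe) outputs;
#' * the cascade — `ann21` detects ischemia (control vs ischemic) from the
#'   magnitudes, and `ann22` grades it (mild vs severe) from the ratios of
#'   change.
#'
#' Each network is selected by 10-fold cross-validation over its
#' architecture grid and scored on the common held-out evaluation split
#' (the split is stratified by severity and shared across networks). The
#' default learning rates follow the reported ratios: the multi-class
#' network trains 20 times slower than `ann22` and half as fast as `ann21`.
#'
#' @param features feature table from [feature_table()].
#' @param seed seed for split, folds and weight initialisation.
#' @param grid1,grid21,grid22 explicit architecture grids (lists of
#'   [mlp_spec()]); by default the grids cross `hidden_layers` with
#'   `hidden_units`.
#' @param hidden_layers,hidden_units default grid axes; the defaults cover
#'   the optima reported for the three networks (5/7, 5/8 and 4/4).
#' @param n_folds cross-validation folds.
#' @param lr1,lr21,lr22 learning rates used when the corresponding grid is
#'   built by default.
#' @param epochs maximum epochs for default grids.
#' @param refit refit winners on the full training split (see [mlp_cv()]).
#' @param with_ann1 also train the multi-class network.
#' @param verbose print progress.
#' @return Object of class `ischemia_classifiers`: the fitted `mlp_cv`
#'   objects (`ann1`, `ann21`, `ann22`), cascade evaluation metrics
#'   (`cascade_metrics`), logistic baselines, Garson importances, and the
#'   shared dataset objects.
#' @export
train_classifiers <- function(features, seed = 1,
                              grid1 = NULL, grid21 = NULL, grid22 = NULL,
                              hidden_layers = c(4, 5),
                              hidden_units = c(4, 7, 8),
                              lr1 = 0.005, lr21 = 0.01, lr22 = 0.1,
                              epochs = 20000, n_folds = 10, refit = FALSE,
                              with_ann1 = TRUE, verbose = FALSE) {
  feats <- pecg_feature_names()
  rfeats <- ratio_feature_names()
  labs <- factor(features$severity, levels = c("control", "mild", "severe"))
  x_mag <- as.matrix(features[feats])
  x_rat <- as.matrix(features[rfeats])

  grid1 <- grid1 %||% mlp_grid(hidden_layers, hidden_units,
                               learning_rate = lr1, epochs = epochs, seed = seed)
  grid21 <- grid21 %||% mlp_grid(hidden_layers, hidden_units,
                                 learning_rate = lr21, epochs = epochs, seed = seed)
  grid22 <- grid22 %||% mlp_grid(hidden_layers, hidden_units,
                                 learning_rate = lr22, epochs = epochs, seed = seed)

  # one master split shared by every network
  ds3 <- ml_dataset(x_mag, labs, n_folds = n_folds, seed = seed)
  detect_labs <- factor(ifelse(labs == "control", "control", "ischemic"),
                        levels = c("control", "ischemic"))
  ds21 <- ds3
  ds21$y <- detect_labs
  ds21$classes <- levels(detect_labs)

  # ann22 sees only ischemic rows, with the master split restricted to them
  isch_rows <- which(labs %in% c("mild", "severe"))
  ds22 <- subset_dataset(x_rat, droplevels(labs[isch_rows]), isch_rows, ds3)

  ann21 <- mlp_cv(ds21, grid21, positive = "ischemic", refit = refit,
                  verbose = verbose)
  ann22 <- mlp_cv(ds22, grid22, positive = "severe", refit = refit,
                  verbose = verbose)
  ann1 <- if (with_ann1) mlp_cv(ds3, grid1, refit = refit, verbose = verbose)

  # cascade decisions on the shared evaluation split
  ev <- ds3$eval
  casc_pred <- cascade_predict(ann21$fit, ann22$fit,
                               x_mag[ev, , drop = FALSE],
                               x_rat[ev, , drop = FALSE])
  cascade_metrics <- classification_metrics(labs[ev], casc_pred)

  log21 <- logistic_baseline(ds21, positive = "ischemic")
  log22 <- logistic_baseline(ds22, positive = "severe")

  structure(list(
    ann1 = ann1, ann21 = ann21, ann22 = ann22,
    cascade_metrics = cascade_metrics,
    cascade_predictions = tibble(truth = labs[ev], pred = casc_pred),
    logistic21 = log21, logistic22 = log22,
    importance = list(
      ann1 = if (with_ann1) garson_importance(ann1$fit),
      ann21 = garson_importance(ann21$fit),
      ann22 = garson_importance(ann22$fit)
    ),
    datasets = list(multiclass = ds3, detect = ds21, grade = ds22),
    seed = seed
  ), class = "ischemia_classifiers")
}

subset_dataset <- function(x, y, rows, master) {
  x <- x[rows, , drop = FALSE] # restrict to the subset, keep index alignment
  tr <- which(rows %in% master$train)
  ev <- which(rows %in% master$eval)
  folds <- integer(length(tr))
  set.seed(master$seed + 1)
  for (cl in levels(y)) {
    pos <- which(y[tr] == cl)
    folds[pos] <- sample(rep_len(seq_len(master$n_folds), length(pos)))
  }
  ctr <- colMeans(x[tr, , drop = FALSE])
  scl <- apply(x[tr, , drop = FALSE], 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(x = x, y = y, train = tr, eval = ev, folds = folds,
                 n_folds = master$n_folds, center = ctr, scale = scl,
                 classes = levels(y), seed = master$seed),
            class = "ml_dataset")
}

#' Cascade prediction: detect, then grade
#'
#' @param fit21 detection network (control vs ischemic, magnitude features).
#' @param fit22 grading network (mild vs severe, ratio features).
#' @param x_mag,x_ratio feature matrices for the same examples.
#' @return Factor with levels control/mild/severe.
#' @export
cascade_predict <- function(fit21, fit22, x_mag, x_ratio) {
  p_isch <- predict(fit21, x_mag)[, 1] > 0.5
  out <- rep("control", nrow(x_mag))
  if (any(p_isch)) {
    p_sev <- predict(fit22, x_ratio[p_isch, , drop = FALSE])[, 1] > 0.5
    out[p_isch] <- ifelse(p_sev, "severe", "mild")
  }
  factor(out, levels = c("control", "mild", "severe"))
}

#' @export
print.ischemia_classifiers <- function(x, ...) {
  cat("<ischemia_classifiers>\n")
  if (!is.null(x$ann1)) {
    cat(sprintf("  ann1    HL %d HU %d  Se %.2f PPV %.2f F1 %.2f\n",
                x$ann1$spec$hidden_layers, x$ann1$spec$hidden_units,
                x$ann1$metrics$se, x$ann1$metrics$ppv, x$ann1$metrics$f1))
  }
  cat(sprintf("  ann21   HL %d HU %d  Se %.2f PPV %.2f F1 %.2f\n",
              x$ann21$spec$hidden_layers, x$ann21$spec$hidden_units,
              x$ann21$metrics$se, x$ann21$metrics$ppv, x$ann21$metrics$f1))
  cat(sprintf("  ann22   HL %d HU %d  Se %.2f PPV %.2f F1 %.2f\n",
              x$ann22$spec$hidden_layers, x$ann22$spec$hidden_units,
              x$ann22$metrics$se, x$ann22$metrics$ppv, x$ann22$metrics$f1))
  cat(sprintf("  cascade Se %.2f PPV %.2f F1 %.2f\n",
              x$cascade_metrics$se, x$cascade_metrics$ppv,
              x$cascade_metrics$f1))
  invisible(x)
}

#' Configuration of a full in-silico study
#'
#' @param n_samples Latin hypercube sample count for the population stage.
#' @param seed master seed.
#' @param n_class_models cap on accepted models carried into the feature
#'   table / classifiers.
#' @param cell_beats pre-pacing beats for single cells.
#' @param cable_beats pacing beats for cables.
#' @param warm_start warm-start cables from single-cell steady states.
#' @param zones region sizes for the zone sweep, cm.
#' @param epochs training epochs cap.
#' @param n_folds cross-validation folds.
#' @param hidden_layers,hidden_units architecture grid axes.
#' @param with_ann1 train the multi-class network too.
#' @param out_dir optional directory to persist CSV artifacts + manifest.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_samples = 10000, seed = 1, n_class_models = Inf,
                         cell_beats = 200, cable_beats = 30,
                         warm_start = FALSE, zones = c(0.5, 1, 1.5, 2),
                         epochs = 20000, n_folds = 10,
                         hidden_layers = c(4, 5), hidden_units = c(4, 7, 8),
                         with_ann1 = TRUE, out_dir = NULL) {
  structure(list(n_samples = n_samples, seed = seed,
                 n_class_models = n_class_models, cell_beats = cell_beats,
                 cable_beats = cable_beats, warm_start = warm_start,
                 zones = zones, epochs = epochs, n_folds = n_folds,
                 hidden_layers = hidden_layers, hidden_units = hidden_units,
                 with_ann1 = with_ann1, out_dir = out_dir),
            class = "study_config")
}

#' Run the full in-silico study
#'
#' Executes the pipeline end to end at the scale set by the configuration:
#' control-population construction, per-severity cable simulations and
#' pseudo-ECG feature extraction, an ischemic-region-size sweep on the
#' baseline model, classifier training/evaluation, and summary tables.
#' When `out_dir` is set, each stage's artifact is written as CSV together
#' with a JSON manifest of the configuration.
#'
#' @param config a [study_config()].
#' @param progress print stage progress.
#' @return List of class `ischemia_study` with elements `population`,
#'   `features`, `sweep`, `classifiers`, `tables`, `config`.
#' @export
run_study <- function(config = study_config(), progress = TRUE) {
  say <- function(...) if (progress) message(sprintf(...))
  say("stage 1/4: population (%d samples)", config$n_samples)
  pop <- build_population(config$n_samples, seed = config$seed,
                          n_beats = config$cell_beats,
                          progress = if (progress) 200 else 0)
  cable_proto <- pacing_protocol(cl = 600, n_beats = config$cable_beats)
  say("stage 2/4: cable features (%d accepted models, cap %s)",
      sum(pop$accepted), format(config$n_class_models))
  feats <- feature_table(pop, n_models = config$n_class_models,
                         protocol = cable_proto,
                         warm_start = config$warm_start,
                         progress = if (progress) 25 else 0)
  say("stage 3/4: zone sweep (baseline model)")
  sweep_tbl <- zone_sweep(zones = config$zones, protocol = cable_proto)
  say("stage 4/4: classifiers")
  clf <- train_classifiers(feats, seed = config$seed, epochs = config$epochs,
                           n_folds = config$n_folds,
                           hidden_layers = config$hidden_layers,
                           hidden_units = config$hidden_units,
                           with_ann1 = config$with_ann1)
  study <- structure(list(population = pop, features = feats,
                          sweep = sweep_tbl, classifiers = clf,
                          config = config),
                     class = "ischemia_study")
  study$tables <- study_tables(study)
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' Summary tables of a completed study
#'
#' @param study an `ischemia_study` from [run_study()].
#' @return List of tibbles: `biomarkers` (population mean and SD of the AP
#'   and pseudo-ECG biomarkers of the control population), `networks` (one
#'   row per trained network: architecture, Se, PPV, F1), `importance`
#'   (Garson importances, one column per network).
#' @export
study_tables <- function(study) {
  if (is.null(study$population) || is.null(study$features)) {
    abort("study is missing the population or feature stage",
          class = "pecgsim_missing_stage")
  }
  ctrl <- dplyr::filter(study$features, .data$severity == "control")
  pop_tbl <- population_summary(study$population)
  pecg_tbl <- tidyr::pivot_longer(
    ctrl[c("cv", "qt_interval", "qrs_duration", "t_duration")],
    dplyr::everything(), names_to = "biomarker") |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  clf <- study$classifiers
  networks <- purrr::imap_dfr(
    list(ann1 = clf$ann1, ann21 = clf$ann21, ann22 = clf$ann22),
    function(cv, nm) {
      if (is.null(cv)) return(NULL)
      tibble(network = nm, hidden_layers = cv$spec$hidden_layers,
             hidden_units = cv$spec$hidden_units,
             se = cv$metrics$se, ppv = cv$metrics$ppv, f1 = cv$metrics$f1)
    })
  networks <- dplyr::bind_rows(
    networks,
    tibble(network = "cascade", hidden_layers = NA, hidden_units = NA,
           se = clf$cascade_metrics$se, ppv = clf$cascade_metrics$ppv,
           f1 = clf$cascade_metrics$f1))
  imp <- purrr::imap_dfr(clf$importance, function(tb, nm) {
    if (is.null(tb)) return(NULL)
    # the grading network consumes ratio features; report per biomarker
    dplyr::mutate(tb, feature = sub("_ratio$", "", .data$feature),
                  network = nm)
  }) |> tidyr::pivot_wider(names_from = "network", values_from = "importance")
  list(biomarkers = dplyr::bind_rows(pop_tbl, pecg_tbl),
       networks = networks, importance = imp)
}

write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_population(study$population, file.path(dir, "population.csv"))
  write.csv(study$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(study$sweep, file.path(dir, "zone_sweep.csv"), row.names = FALSE)
  for (nm in names(study$tables)) {
    write.csv(study$tables[[nm]], file.path(dir, paste0("table_", nm, ".csv")),
              row.names = FALSE)
  }
  manifest <- list(
    config = unclass(study$config),
    n_accepted = sum(study$population$accepted),
    acceptance_fraction = attr(study$population, "acceptance_fraction"),
    artifacts = c("population.csv", "features.csv", "zone_sweep.csv",
                  paste0("table_", names(study$tables), ".csv")),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("pecgsim"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
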