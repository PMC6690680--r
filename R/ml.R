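#' Assemble a train/evaluation dataset for the classifiers
#'
#' Splits the examples into a training set (75%) and an evaluation set
#' (25%), stratified by class so every class is represented in both, and
#' assigns 10 cross-validation folds on the training set. Per-feature
#' z-score normalisation statistics are fitted on the training set only.
#'
#' @param features numeric matrix or data frame of features (one row per
#'   example).
#' @param labels factor (or coercible) of class labels, one per example.
#' @param split_prop training fraction.
#' @param n_folds number of cross-validation folds on the training set.
#' @param seed integer seed controlling split and fold assignment.
#' @return An object of class `ml_dataset`: list with `x`, `y`, `train`,
#'   `eval` (row indices), `folds` (fold id per training row), `center`,
#'   `scale`, `classes`.
#' @examples
#' d <- ml_dataset(matrix(rnorm(60), 30), rep(c("a", "b"), 15), seed = 1)
#' table(d$y[d$eval])
#' @export
ml_dataset <- function(features, labels, split_prop = 0.75, n_folds = 10,
                       seed = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- factor(labels)
  if (nrow(x) != length(y)) {
    abort("features and labels disagree in length",
          class = "pecgsim_invalid_parameter")
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- round(split_prop * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  eval_idx <- setdiff(seq_len(nrow(x)), train)
  folds <- integer(length(train))
  # stratified folds
  for (cl in levels(y)) {
    pos <- which(y[train] == cl)
    folds[pos] <- sample(rep_len(seq_len(n_folds), length(pos)))
  }
  ctr <- colMeans(x[train, , drop = FALSE])
  scl <- apply(x[train, , drop = FALSE], 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(x = x, y = y, train = train, eval = eval_idx, folds = folds,
                 n_folds = n_folds, center = ctr, scale = scl,
                 classes = levels(y), seed = seed),
            class = "ml_dataset")
}

normalize_x <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center), 2, scale, `/`)
}

#' Multilayer-perceptron hyperparameters
#'
#' Fully-connected perceptron with rectified-linear hidden units and
#' sigmoid output units, trained by full-batch gradient descent on a
#' weight-decay-regularised binary cross-entropy cost.
#'
#' @param hidden_layers number of hidden layers (HL).
#' @param hidden_units units per hidden layer (HU).
#' @param learning_rate gradient-descent step size.
#' @param weight_decay L2 penalty coefficient on the weights.
#' @param epochs maximum full-batch epochs.
#' @param seed seed for the He-scaled uniform weight initialisation.
#' @param tol relative cost-improvement tolerance for early stopping.
#' @param patience epochs over which the relative improvement is assessed.
#' @return Object of class `mlp_spec`.
#' @examples
#' mlp_spec(hidden_layers = 4, hidden_units = 4, learning_rate = 0.1)
#' @export
mlp_spec <- function(hidden_layers = 1, hidden_units = 4, learning_rate = 0.1,
                     weight_decay = 1e-4, epochs = 20000, seed = 1,
                     tol = 1e-8, patience = 500) {
  if (hidden_layers < 1 || hidden_units < 1) {
    abort("need at least one hidden layer and one hidden unit",
          class = "pecgsim_invalid_parameter")
  }
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = seed, tol = tol,
                 patience = as.integer(patience)),
            class = "mlp_spec")
}

#' Grid of MLP hyperparameters
#'
#' @param hidden_layers,hidden_units vectors crossed into a grid.
#' @param ... further arguments passed to every [mlp_spec()].
#' @return List of `mlp_spec`s.
#' @export
mlp_grid <- function(hidden_layers = 1:6, hidden_units = 2:10, ...) {
  g <- expand.grid(hl = hidden_layers, hu = hidden_units)
  purrr::pmap(g, function(hl, hu) mlp_spec(hl, hu, ...))
}

# seeded random small-value initialisation, scaled for rectified-linear
# stacks (He-style uniform, +-sqrt(6 / fan_in)): a fixed +-0.1 window makes
# the forward signal vanish through 4-5 ReLU layers and full-batch descent
# stalls on a constant-output plateau
init_weights <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    r <- sqrt(6 / sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

# internal fast path: activations stored transposed (units x examples) so
# that bias vectors recycle down columns without sweep()
fwd_t <- function(weights, biases, A) {
  L <- length(weights)
  H <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    Z <- crossprod(weights[[l]], A) + biases[[l]]
    A <- Z * (Z > 0)
    H[[l]] <- A
  }
  Z <- crossprod(weights[[L]], A) + biases[[L]]
  list(output = 1 / (1 + exp(-Z)), hidden = H)
}

grad_t <- function(weights, biases, X, Y, lambda) {
  L <- length(weights)
  fw <- fwd_t(weights, biases, X)
  n <- ncol(X)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- (fw$output - Y) / n # sigmoid + summed binary cross-entropy
  for (l in L:1) {
    a_prev <- if (l == 1) X else fw$hidden[[l - 1]]
    dW[[l]] <- tcrossprod(a_prev, delta) + 2 * lambda * weights[[l]]
    db[[l]] <- rowSums(delta)
    if (l > 1) delta <- (weights[[l]] %*% delta) * (a_prev > 0)
  }
  eps <- 1e-12
  p <- pmin(pmax(fw$output, eps), 1 - eps)
  cost <- -mean(colSums(Y * log(p) + (1 - Y) * log(1 - p))) +
    lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  list(dW = dW, db = db, cost = cost)
}

#' Forward propagation through an MLP
#'
#' Affine maps with rectified-linear activations on hidden layers and a
#' sigmoid on the output layer.
#'
#' @param weights list of weight matrices (`from x to`).
#' @param biases list of bias vectors.
#' @param x numeric matrix of (already normalised) inputs, one row per
#'   example.
#' @return List with `output` (matrix of sigmoid activations in (0,1)) and
#'   `hidden` (list of hidden activations, for backpropagation).
#' @export
mlp_forward <- function(weights, biases, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(weights[[1]])) {
    abort("feature width does not match the network input width",
          class = "pecgsim_invalid_parameter")
  }
  fw <- fwd_t(weights, biases, t(x))
  list(output = t(fw$output), hidden = lapply(fw$hidden, t))
}

mlp_cost <- function(out, y, W, lambda) {
  eps <- 1e-12
  p <- pmin(pmax(out, eps), 1 - eps)
  bce <- -mean(rowSums(y * log(p) + (1 - y) * log(1 - p)))
  bce + lambda * sum(vapply(W, function(w) sum(w^2), numeric(1)))
}

#' Gradient of the regularised cross-entropy cost by backpropagation
#'
#' @param weights,biases network parameters.
#' @param x normalised input matrix; `y` 0/1 target matrix.
#' @param y target matrix (one column per output unit).
#' @param lambda weight-decay coefficient.
#' @return List with `dW`, `db` and the scalar `cost`.
#' @export
mlp_gradient <- function(weights, biases, x, y, lambda) {
  grad_t(weights, biases, t(as.matrix(x)), t(as.matrix(y)), lambda)
}

one_hot <- function(y, classes) {
  if (length(classes) == 2) {
    matrix(as.numeric(y == classes[2]), ncol = 1,
           dimnames = list(NULL, classes[2]))
  } else {
    m <- sapply(classes, function(cl) as.numeric(y == cl))
    matrix(m, ncol = length(classes), dimnames = list(NULL, classes))
  }
}

#' Train a multilayer perceptron
#'
#' Full-batch gradient descent on the weight-decay-regularised binary
#' cross-entropy, with deterministic seeded initialisation and early
#' stopping when the smoothed cost stops improving. Binary problems use one
#' sigmoid output (the second class is the positive one); K-class problems
#' use K sigmoid outputs against one-hot targets and arg-max decisions.
#'
#' @param x raw feature matrix (training examples).
#' @param y factor of labels.
#' @param spec an [mlp_spec()].
#' @param center,scale normalisation statistics (z-score; fitted upstream on
#'   training data).
#' @param classes class levels (defaults to `levels(y)`).
#' @return Object of class `mlp_fit`: weights, biases, spec, classes,
#'   normalisation, cost history (one entry per epoch run).
#' @examples
#' x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
#' y <- factor(c("a", "b", "b", "a")) # XOR
#' fit <- mlp_fit(x, y, mlp_spec(1, 4, 0.5, 0, epochs = 5000, seed = 3),
#'                center = c(0.5, 0.5), scale = c(0.5, 0.5))
#' predict(fit, x, type = "class")
#' @export
mlp_fit <- function(x, y, spec, center = NULL, scale = NULL, classes = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- classes %||% levels(y)
  if (is.null(center)) center <- rep(0, ncol(x))
  if (is.null(scale)) scale <- rep(1, ncol(x))
  xn <- t(normalize_x(x, center, scale))
  Y <- t(one_hot(y, classes))
  sizes <- c(nrow(xn), rep(spec$hidden_units, spec$hidden_layers), nrow(Y))
  par <- init_weights(sizes, spec$seed)
  W <- par$W; b <- par$b
  history <- numeric(spec$epochs)
  last_check <- Inf
  epoch_run <- spec$epochs
  for (e in seq_len(spec$epochs)) {
    g <- grad_t(W, b, xn, Y, spec$weight_decay)
    if (!is.finite(g$cost)) {
      abort("training diverged (non-finite cost); try a smaller learning rate",
            class = "pecgsim_training_failure")
    }
    for (l in seq_along(W)) {
      W[[l]] <- W[[l]] - spec$learning_rate * g$dW[[l]]
      b[[l]] <- b[[l]] - spec$learning_rate * g$db[[l]]
    }
    history[e] <- g$cost
    if (e %% spec$patience == 0) {
      if (is.finite(last_check) &&
          (last_check - g$cost) / max(abs(last_check), 1e-12) < spec$tol) {
        epoch_run <- e
        break
      }
      last_check <- g$cost
    }
  }
  structure(list(weights = W, biases = b, spec = spec, classes = classes,
                 center = center, scale = scale,
                 feature_names = colnames(x),
                 history = history[seq_len(epoch_run)],
                 n_train = nrow(x)),
            class = "mlp_fit")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("<mlp_fit> %d-%s-%d (HL %d, HU %d), %d epochs, final cost %.4g\n",
              nrow(x$weights[[1]]),
              paste(rep(x$spec$hidden_units, x$spec$hidden_layers), collapse = "-"),
              ncol(x$weights[[length(x$weights)]]),
              x$spec$hidden_layers, x$spec$hidden_units,
              length(x$history), tail(x$history, 1)))
  invisible(x)
}

#' Predict from a fitted MLP
#'
#' @param object an `mlp_fit`.
#' @param newdata raw feature matrix.
#' @param type `"prob"` for sigmoid activations, `"class"` for decisions
#'   (0.5 threshold for binary, arg-max for multi-class).
#' @param ... unused.
#' @return Matrix of probabilities or factor of classes.
#' @export
predict.mlp_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  xn <- normalize_x(as.matrix(newdata), object$center, object$scale)
  p <- mlp_forward(object$weights, object$biases, xn)$output
  if (type == "prob") return(p)
  cl <- if (length(object$classes) == 2) {
    object$classes[1 + (p[, 1] > 0.5)]
  } else {
    object$classes[max.col(p, ties.method = "first")]
  }
  factor(cl, levels = object$classes)
}

#' Classification metrics: sensitivity, PPV and F1
#'
#' Binary: Se = TP/(TP+FN), PPV = TP/(TP+FP) for the positive class. For
#' more than two classes, Se and PPV are macro-averaged over the classes
#' treated one-vs-rest. F1 is the harmonic mean of the reported Se and PPV.
#' All values are percentages.
#'
#' @param truth,pred factors over the same class set.
#' @param positive the positive class for binary tasks (defaults to the
#'   second level).
#' @return One-row tibble `se`, `ppv`, `f1` (%), with the confusion matrix
#'   as attribute `"confusion"`.
#' @examples
#' classification_metrics(factor(c(1, 1, 0, 0)), factor(c(1, 0, 0, 0)),
#'                        positive = "1")
#' @export
classification_metrics <- function(truth, pred, positive = NULL) {
  if (!is.factor(truth)) truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  missing_cls <- setdiff(levels(truth), unique(as.character(truth)))
  if (length(missing_cls) > 0) {
    abort(paste("metrics undefined: class absent from the evaluation set:",
                paste(missing_cls, collapse = ", ")),
          class = "pecgsim_undefined_metric")
  }
  cm <- table(truth = truth, pred = pred)
  per_class <- function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    c(se = tp / (tp + fn), ppv = if (tp + fp == 0) 0 else tp / (tp + fp))
  }
  if (nlevels(truth) == 2) {
    positive <- positive %||% levels(truth)[2]
    m <- per_class(positive)
  } else {
    m <- rowMeans(sapply(levels(truth), per_class))
  }
  se <- 100 * m[["se"]]; ppv <- 100 * m[["ppv"]]
  f1 <- if (se + ppv == 0) 0 else 2 * se * ppv / (se + ppv)
  out <- tibble(se = se, ppv = ppv, f1 = f1)
  attr(out, "confusion") <- cm
  out
}

params_of <- function(spec, p_in, k_out) {
  sizes <- c(p_in, rep(spec$hidden_units, spec$hidden_layers), k_out)
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}

#' Cross-validated hyperparameter selection for an MLP
#'
#' For every candidate architecture, performs k-fold cross-validation on
#' the training split; the selection criterion is the mean validation F1
#' across folds (ties broken toward fewer parameters). The weights that
#' performed best during cross-validation (the best fold of the winning
#' architecture) are then tested once on the held-out evaluation set;
#' `refit = TRUE` retrains the winning architecture on the full training
#' split instead.
#'
#' @param dataset an [ml_dataset()].
#' @param grid list of [mlp_spec()]s.
#' @param positive positive class for binary metrics.
#' @param refit retrain the selected architecture on the full training set
#'   before evaluation.
#' @param verbose print per-spec progress.
#' @return Object of class `mlp_cv`: `fit` (the selected `mlp_fit`),
#'   `cv_report` (tibble: architecture, mean/sd validation F1), and
#'   `metrics` (evaluation-set Se/PPV/F1).
#' @export
mlp_cv <- function(dataset, grid, positive = NULL, refit = FALSE,
                   verbose = FALSE) {
  if (length(grid) == 0) {
    abort("empty hyperparameter grid", class = "pecgsim_invalid_parameter")
  }
  stopifnot(inherits(dataset, "ml_dataset"))
  xtr <- dataset$x[dataset$train, , drop = FALSE]
  ytr <- droplevels(dataset$y[dataset$train])
  if (min(table(ytr)) < dataset$n_folds) {
    warn("fewer training examples per class than folds")
  }
  report <- list()
  best <- NULL
  for (si in seq_along(grid)) {
    spec <- grid[[si]]
    fold_f1 <- numeric(dataset$n_folds)
    fold_fits <- vector("list", dataset$n_folds)
    for (k in seq_len(dataset$n_folds)) {
      tr <- dataset$folds != k
      fit <- mlp_fit(xtr[tr, , drop = FALSE], ytr[tr], spec,
                     center = dataset$center, scale = dataset$scale,
                     classes = levels(ytr))
      pred <- predict(fit, xtr[!tr, , drop = FALSE], type = "class")
      fold_f1[k] <- classification_metrics(ytr[!tr], pred, positive)$f1
      fold_fits[[k]] <- fit
    }
    mf1 <- mean(fold_f1)
    report[[si]] <- tibble(hidden_layers = spec$hidden_layers,
                           hidden_units = spec$hidden_units,
                           mean_f1 = mf1, sd_f1 = sd(fold_f1),
                           n_params = params_of(spec, ncol(xtr),
                                                if (nlevels(ytr) == 2) 1 else nlevels(ytr)))
    if (verbose) {
      message(sprintf("HL %d HU %d: CV F1 %.2f", spec$hidden_layers,
                      spec$hidden_units, mf1))
    }
    better <- is.null(best) || mf1 > best$mf1 + 1e-9 ||
      (abs(mf1 - best$mf1) <= 1e-9 &&
         report[[si]]$n_params < best$n_params)
    if (better) {
      best <- list(spec = spec, mf1 = mf1, n_params = report[[si]]$n_params,
                   fit = fold_fits[[which.max(fold_f1)]])
    }
  }
  fit <- if (refit) {
    mlp_fit(xtr, ytr, best$spec, center = dataset$center,
            scale = dataset$scale, classes = levels(ytr))
  } else {
    best$fit
  }
  xev <- dataset$x[dataset$eval, , drop = FALSE]
  yev <- factor(dataset$y[dataset$eval], levels = levels(ytr))
  metrics <- classification_metrics(yev, predict(fit, xev, type = "class"),
                                    positive)
  structure(list(fit = fit, spec = best$spec,
                 cv_report = dplyr::bind_rows(report), metrics = metrics),
            class = "mlp_cv")
}

#' @export
print.mlp_cv <- function(x, ...) {
  cat(sprintf("<mlp_cv> selected HL %d, HU %d; eval Se %.2f%%, PPV %.2f%%, F1 %.2f%%\n",
              x$spec$hidden_layers, x$spec$hidden_units,
              x$metrics$se, x$metrics$ppv, x$metrics$f1))
  invisible(x)
}

#' Garson-Goh relative importance of input features
#'
#' Attributes the network's decisions to its inputs through the magnitudes
#' of its weights: absolute weight matrices of all hidden layers are
#' multiplied into a single input-to-last-hidden contribution matrix, each
#' hidden pathway is normalised by its total inbound contribution, weighted
#' by its absolute outbound (output-layer) weight, summed per input and
#' renormalised to sum to one. With a single hidden layer this is Garson's
#' original tableau.
#'
#' @param fit an `mlp_fit`.
#' @return Tibble `feature`, `importance` (nonnegative, sums to 1).
#' @export
garson_importance <- function(fit) {
  W <- lapply(fit$weights, abs)
  L <- length(W)
  P <- W[[1]]
  if (L > 2) for (l in 2:(L - 1)) P <- P %*% W[[l]]
  out_w <- rowSums(W[[L]])
  colsum <- colSums(P)
  colsum[colsum == 0] <- 1
  contrib <- sweep(P, 2, colsum, `/`) %*% out_w
  imp <- as.vector(contrib)
  imp <- imp / sum(imp)
  tibble(feature = fit$feature_names %||% paste0("x", seq_along(imp)),
         importance = imp)
}

#' Regularised logistic-regression baseline
#'
#' Ridge-regularised logistic regression (binomial, or multinomial for more
#' than two classes) trained on the same normalised training split and
#' scored on the same evaluation split as the neural networks.
#'
#' @param dataset an [ml_dataset()].
#' @param positive positive class for binary metrics.
#' @param lambda ridge penalty.
#' @return List with `metrics` (Se/PPV/F1 tibble) and the fitted `glmnet`
#'   object.
#' @export
logistic_baseline <- function(dataset, positive = NULL, lambda = 1e-3) {
  xtr <- normalize_x(dataset$x[dataset$train, , drop = FALSE],
                     dataset$center, dataset$scale)
  ytr <- droplevels(dataset$y[dataset$train])
  fam <- if (nlevels(ytr) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(xtr, ytr, family = fam, alpha = 0,
                        lambda = lambda, standardize = FALSE)
  xev <- normalize_x(dataset$x[dataset$eval, , drop = FALSE],
                     dataset$center, dataset$scale)
  pr <- predict(fit, xev, type = "class")
  pred <- factor(as.character(pr[, 1]), levels = levels(ytr))
  yev <- factor(dataset$y[dataset$eval], levels = levels(ytr))
  list(metrics = classification_metrics(yev, pred, positive), fit = fit)
}

#' @rdname tidy.mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble(hidden_layers = x$spec$hidden_layers,
         hidden_units = x$spec$hidden_units,
         learning_rate = x$spec$learning_rate,
         weight_decay = x$spec$weight_decay,
         epochs_run = length(x$history),
         final_cost = tail(x$history, 1),
         n_train = x$n_train)
}

#' Tidiers for fitted MLPs
#'
#' `tidy()` returns one row per weight; `glance()` a one-row model summary.
#'
#' @param x an `mlp_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mlp_fit <- function(x, ...) {
  purrr::imap_dfr(x$weights, function(w, l) {
    tibble(layer = l,
           from = rep(seq_len(nrow(w)), ncol(w)),
           to = rep(seq_len(ncol(w)), each = nrow(w)),
           weight = as.vector(w))
  })
}

#' Serialize a fitted MLP to JSON / restore it
#'
#' Stores layer shapes, weights, biases, normalisation statistics, classes
#' and the hyperparameters, so a trained network is portable as plain text.
#'
#' @param fit an `mlp_fit`.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_mlp()` returns the restored `mlp_fit`.
#' @export
write_mlp <- function(fit, path) {
  stopifnot(inherits(fit, "mlp_fit"))
  payload <- list(
    spec = unclass(fit$spec),
    classes = fit$classes,
    feature_names = fit$feature_names,
    center = fit$center, scale = fit$scale,
    weights = lapply(fit$weights, function(w) list(dim = dim(w),
                                                   values = as.vector(w))),
    biases = fit$biases,
    final_cost = tail(fit$history, 1)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(mlp_spec, p$spec[c("hidden_layers", "hidden_units",
                                     "learning_rate", "weight_decay",
                                     "epochs", "seed", "tol", "patience")])
  W <- lapply(seq_len(nrow(p$weights)), function(i) {
    matrix(p$weights$values[[i]], p$weights$dim[[i]][1], p$weights$dim[[i]][2])
  })
  structure(list(weights = W, biases = p$biases, spec = spec,
                 classes = p$classes, center = p$center, scale = p$scale,
                 feature_names = p$feature_names,
                 history = p$final_cost, n_train = NA_integer_),
            class = "mlp_fit")
}
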