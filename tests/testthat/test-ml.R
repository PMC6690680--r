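test_that("forward propagation matches pencil-and-paper evaluation", {
  # 1 input -> 1 hidden (relu) -> 1 sigmoid output, hand-set weights
  W <- list(matrix(2), matrix(-1.5))
  b <- list(0.5, 0.25)
  x <- matrix(c(-1, 0.6), ncol = 1)
  h <- pmax(2 * x + 0.5, 0)
  expected <- 1 / (1 + exp(-(-1.5 * h + 0.25)))
  got <- mlp_forward(W, b, x)$output
  expect_equal(as.vector(got), as.vector(expected), tolerance = 1e-15)
})

test_that("all-zero parameters produce 0.5 everywhere", {
  W <- list(matrix(0, 3, 4), matrix(0, 4, 2))
  b <- list(rep(0, 4), rep(0, 2))
  out <- mlp_forward(W, b, matrix(rnorm(15), 5, 3))$output
  expect_true(all(out == 0.5))
})

test_that("all-positive weights give a monotone response", {
  set.seed(1)
  W <- list(matrix(runif(6, 0.1, 1), 2, 3), matrix(runif(3, 0.1, 1), 3, 1))
  b <- list(rep(0.1, 3), 0.1)
  lo <- mlp_forward(W, b, matrix(c(0.1, 0.5), 1))$output
  hi <- mlp_forward(W, b, matrix(c(0.9, 0.5), 1))$output
  expect_gt(hi, lo)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(42)
  x <- matrix(rnorm(12), 4, 3)
  y <- matrix(c(1, 0, 0, 1), 4, 1)
  lambda <- 1e-3
  for (arch in list(c(1, 3), c(4, 4), c(5, 8))) {
    sizes <- c(3, rep(arch[2], arch[1]), 1)
    par <- pecgsim:::init_weights(sizes, seed = 7)
    g <- mlp_gradient(par$W, par$b, x, y, lambda)
    cost_of <- function(W, b) {
      out <- mlp_forward(W, b, x)$output
      p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
      -mean(rowSums(y * log(p) + (1 - y) * log(1 - p))) +
        lambda * sum(vapply(W, function(w) sum(w^2), numeric(1)))
    }
    eps <- 1e-5
    worst <- 0
    for (l in seq_along(par$W)) {
      idx <- cbind(sample(nrow(par$W[[l]]), 3, replace = TRUE),
                   sample(ncol(par$W[[l]]), 3, replace = TRUE))
      for (k in seq_len(nrow(idx))) {
        Wp <- par$W; Wm <- par$W
        Wp[[l]][idx[k, 1], idx[k, 2]] <- Wp[[l]][idx[k, 1], idx[k, 2]] + eps
        Wm[[l]][idx[k, 1], idx[k, 2]] <- Wm[[l]][idx[k, 1], idx[k, 2]] - eps
        fd <- (cost_of(Wp, par$b) - cost_of(Wm, par$b)) / (2 * eps)
        an <- g$dW[[l]][idx[k, 1], idx[k, 2]]
        worst <- max(worst, abs(fd - an) / max(abs(fd), 1e-8))
      }
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("the network learns XOR", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  y <- factor(c("off", "on", "on", "off"))
  solved <- FALSE
  for (s in 1:10) {
    fit <- mlp_fit(x, y, mlp_spec(1, 4, learning_rate = 1, weight_decay = 0,
                                  epochs = 5000, seed = s))
    if (all(predict(fit, x, type = "class") == y)) {
      solved <- TRUE
      break
    }
  }
  expect_true(solved)
})

test_that("strong weight decay shrinks weights and pulls outputs to 0.5", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("a", "b"), 10))
  fit <- mlp_fit(x, y, mlp_spec(1, 4, learning_rate = 0.05, weight_decay = 5,
                                epochs = 2000, seed = 1))
  expect_lt(max(abs(unlist(fit$weights))), 1e-3)
  expect_true(all(abs(predict(fit, x) - 0.5) < 0.01))
})

test_that("training cost decreases over 50-epoch windows", {
  d <- separable_dataset()
  fit <- mlp_fit(d$x[d$train, ], d$y[d$train],
                 mlp_spec(1, 4, 0.1, epochs = 1000, seed = 1),
                 center = d$center, scale = d$scale)
  h <- fit$history
  win <- sapply(split(h, (seq_along(h) - 1) %/% 50), mean)
  expect_true(all(diff(win) <= 1e-9))
})

test_that("classification metrics follow their definitions", {
  # TP = 95, FN = 5, FP = 5 -> Se = PPV = F1 = 95%
  truth <- factor(c(rep("pos", 100), rep("neg", 100)), c("neg", "pos"))
  pred <- factor(c(rep("pos", 95), rep("neg", 5),
                   rep("neg", 95), rep("pos", 5)), c("neg", "pos"))
  m <- classification_metrics(truth, pred, positive = "pos")
  expect_equal(m$se, 95)
  expect_equal(m$ppv, 95)
  expect_equal(m$f1, 95)
  # perfect predictions
  mp <- classification_metrics(truth, truth, positive = "pos")
  expect_equal(unlist(mp), c(se = 100, ppv = 100, f1 = 100))
  # all-positive predictor on balanced data: Se 100, PPV 50
  ap <- classification_metrics(truth, factor(rep("pos", 200), c("neg", "pos")),
                               positive = "pos")
  expect_equal(ap$se, 100)
  expect_equal(ap$ppv, 50)
  # F1 is the harmonic mean of Se and PPV
  expect_equal(ap$f1, 2 * 100 * 50 / 150)
})

test_that("metrics error when a class is absent from the evaluation set", {
  truth <- factor(rep("a", 5), levels = c("a", "b"))
  expect_error(classification_metrics(truth, truth),
               class = "pecgsim_undefined_metric")
})

test_that("splits are reproducible, disjoint and leak-free", {
  x <- matrix(rnorm(200), 100, 2)
  y <- rep(c("u", "v"), 50)
  d1 <- ml_dataset(x, y, seed = 4)
  d2 <- ml_dataset(x, y, seed = 4)
  expect_identical(d1$train, d2$train)
  expect_identical(d1$folds, d2$folds)
  expect_length(intersect(d1$train, d1$eval), 0)
  expect_equal(sort(c(d1$train, d1$eval)), 1:100)
  # normalisation statistics depend on the training rows only
  expect_equal(d1$center, colMeans(x[d1$train, ]))
  x2 <- x
  x2[d1$eval, ] <- x2[d1$eval, ] + 100 # corrupt evaluation rows
  d3 <- ml_dataset(x2, y, seed = 4)
  expect_equal(d3$center, d1$center)
  expect_equal(d3$scale, d1$scale)
})

test_that("a one-spec grid is selected and separable data reach 100%", {
  d <- separable_dataset()
  cv <- mlp_cv(d, list(mlp_spec(1, 3, 0.5, epochs = 2000, seed = 1)),
               positive = "pos")
  expect_equal(cv$spec$hidden_units, 3)
  expect_equal(cv$metrics$f1, 100)
  expect_error(mlp_cv(d, list()), class = "pecgsim_invalid_parameter")
})

test_that("Garson importance matches a hand-worked single-hidden-layer tableau", {
  # 3 inputs, 2 hidden, 1 output with fixed weights
  W1 <- matrix(c(0.8, -0.2, 0.4,
                 0.1, 0.6, -0.3), nrow = 3)
  W2 <- matrix(c(0.7, -0.5), nrow = 2)
  fit <- structure(list(weights = list(W1, W2),
                        feature_names = c("a", "b", "c")),
                   class = "mlp_fit")
  # manual tableau: c_ij = |w_ij| / sum_i |w_ij| * |v_j|
  aW1 <- abs(W1); aW2 <- abs(W2)
  r <- matrix(0, 3, 2)
  for (j in 1:2) {
    for (i in 1:3) r[i, j] <- aW1[i, j] / sum(aW1[, j]) * aW2[j, 1]
  }
  expected <- rowSums(r) / sum(r)
  got <- garson_importance(fit)
  expect_equal(got$importance, expected, tolerance = 1e-12)
  expect_equal(sum(got$importance), 1, tolerance = 1e-12)
})

test_that("Garson importance respects symmetry and dead inputs", {
  # two mirror-identical inputs
  W1 <- matrix(c(0.5, 0.5, -0.7, -0.7), nrow = 2, byrow = FALSE)
  W2 <- matrix(c(0.3, 0.9), nrow = 2)
  fit <- structure(list(weights = list(W1, W2), feature_names = c("p", "q")),
                   class = "mlp_fit")
  imp <- garson_importance(fit)$importance
  expect_equal(imp, c(0.5, 0.5), tolerance = 1e-12)
  # an input with all-zero first-layer weights has zero importance
  W1z <- matrix(c(0.5, 0, 0.3, 0), nrow = 2, byrow = TRUE)
  fitz <- structure(list(weights = list(t(W1z), W2), feature_names = c("p", "q")),
                    class = "mlp_fit")
  impz <- garson_importance(fitz)$importance
  expect_equal(impz[2], 0, tolerance = 1e-12)
  expect_equal(sum(impz), 1, tolerance = 1e-12)
})

test_that("multi-layer Garson importances are nonnegative and sum to one", {
  d <- separable_dataset()
  fit <- mlp_fit(d$x[d$train, ], d$y[d$train],
                 mlp_spec(3, 5, 0.2, epochs = 300, seed = 2),
                 center = d$center, scale = d$scale)
  imp <- garson_importance(fit)$importance
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1, tolerance = 1e-12)
})

test_that("the logistic baseline nails separable data and is at chance on noise", {
  d <- separable_dataset()
  expect_gt(logistic_baseline(d, positive = "pos")$metrics$f1, 99)
  set.seed(8)
  xr <- matrix(rnorm(400), 200, 2)
  yr <- sample(rep(c("x", "y"), 100))
  dr <- ml_dataset(xr, yr, seed = 8)
  m <- logistic_baseline(dr, positive = "y")$metrics
  expect_lt(m$f1, 75)
})

test_that("tidiers summarise fitted networks", {
  d <- separable_dataset()
  fit <- mlp_fit(d$x[d$train, ], d$y[d$train],
                 mlp_spec(2, 3, 0.2, epochs = 100, seed = 1),
                 center = d$center, scale = d$scale)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3 + 3 * 3 + 3 * 1)
  gl <- glance(fit)
  expect_equal(gl$hidden_layers, 2)
  expect_lte(gl$epochs_run, 100)
})

test_that("fitted networks round-trip through JSON", {
  d <- separable_dataset()
  fit <- mlp_fit(d$x[d$train, ], d$y[d$train],
                 mlp_spec(2, 3, 0.2, epochs = 200, seed = 1),
                 center = d$center, scale = d$scale)
  path <- tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(predict(back, d$x[d$eval, ], type = "class"),
                   predict(fit, d$x[d$eval, ], type = "class"))
  unlink(path)
})
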