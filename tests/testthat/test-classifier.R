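# Convolutional classifier: architecture, gradients, training, metrics.

# small fast config for unit tests
fast_config <- function(...) {
  args <- utils::modifyList(
    list(
      filters = c(4L, 6L), dense = c(8L, 1L), epochs = 30L,
      patience = 5L, batch_size = 32L, seed = 7L
    ),
    list(...)
  )
  do.call(classifier_config, args)
}

random_features <- function(n, seed = 1, signal = 0) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  ft <- tibble::tibble(label = ifelse(y == 1, "core", "decoy"))
  for (k in c("s", "e", "h")) {
    for (j in 0:9) {
      ft[[paste0(k, "_", j)]] <- pmin(pmax(
        runif(n) + signal * y * (k != "e"), 0
      ), 1)
    }
  }
  ft
}

test_that("model architecture has 2 conv + 2 dense layers and valid outputs", {
  m <- build_model(fast_config())
  lay <- tidy(m)
  expect_equal(lay$layer, c("conv1", "conv2", "dense1", "dense2"))
  expect_equal(sum(lay$parameters), m$n_parameters)

  x <- as_model_input(random_features(16, seed = 2))
  p <- surfcomp:::nn_forward(m, x$x)$p
  expect_true(all(p >= 0 & p <= 1))

  # deterministic at eval (no dropout)
  p2 <- surfcomp:::nn_forward(m, x$x)$p
  expect_identical(p, p2)

  # fixed seed -> identical initial weights
  m2 <- build_model(fast_config())
  expect_identical(m$weights, m2$weights)

  # kernel larger than the padded input is rejected
  expect_error(
    build_model(classifier_config(kernel = c(13L, 13L))),
    class = "surfcomp_config_error"
  )
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- classifier_config(
    filters = c(2L, 3L), dense = c(4L, 1L),
    dropout = 0, seed = 3
  )
  m <- build_model(cfg, input_shape = c(3L, 10L))
  set.seed(4)
  # jitter all parameters off zero: with zero biases the ReLU
  # pre-activations contain exact zeros, where the central difference sits
  # on the kink and disagrees with any one-sided subgradient
  m$weights <- lapply(m$weights, function(w) w + rnorm(length(w), sd = 0.05))
  X <- matrix(runif(5 * 30), 5, 30)
  y <- matrix(c(1, 0, 1, 1, 0), ncol = 1)
  fwd <- surfcomp:::nn_forward(m, X)
  grads <- surfcomp:::nn_backward(m, X, y, fwd)
  loss_at <- function(model) {
    surfcomp:::bce_loss(surfcomp:::nn_forward(model, X)$p, y)
  }
  eps <- 1e-6
  for (nm in names(m$weights)) {
    w <- m$weights[[nm]]
    picks <- if (length(w) > 6) {
      set.seed(5)
      sample(length(w), 6)
    } else {
      seq_along(w)
    }
    for (i in picks) {
      mp <- m
      mp$weights[[nm]][i] <- w[i] + eps
      mm <- m
      mm$weights[[nm]][i] <- w[i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num,
        tolerance = 1e-4,
        label = paste("grad", nm, i)
      )
    }
  }
})

test_that("training separates linearly separable features", {
  ft <- random_features(400, seed = 6, signal = 0.6)
  sp <- split_dataset(ft, seed = 1)
  m <- train_classifier(build_model(fast_config(epochs = 50L)), sp$train, sp$val)
  hist <- m$history
  expect_gt(hist$train_acc[nrow(hist)], 0.95)
  expect_true(m$trained)
  g <- glance(m)
  expect_equal(g$epochs_run, nrow(hist))
})

test_that("shuffled labels give chance-level validation AUC", {
  ft <- random_features(600, seed = 8, signal = 0) # no signal at all
  sp <- split_dataset(ft, seed = 2)
  m <- train_classifier(build_model(fast_config(epochs = 15L)), sp$train, sp$val)
  pv <- predict(m, sp$val)
  expect_lt(abs(roc_auc(pv$score, pv$truth) - 0.5), 0.18)
})

test_that("training is reproducible under a fixed seed", {
  ft <- random_features(120, seed = 9, signal = 0.3)
  sp <- split_dataset(ft, seed = 3)
  m1 <- train_classifier(build_model(fast_config(epochs = 5L)), sp$train, sp$val)
  m2 <- train_classifier(build_model(fast_config(epochs = 5L)), sp$train, sp$val)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("prediction handles edge cases and refuses unnormalized input", {
  ft <- random_features(60, seed = 10, signal = 0.3)
  m <- train_classifier(build_model(fast_config(epochs = 3L)), ft, NULL)
  # constant-input batch -> constant scores
  const <- ft[rep(1, 5), ]
  pc <- predict(m, const)
  expect_equal(length(unique(pc$score)), 1)
  # empty batch -> empty set
  expect_equal(nrow(predict(m, ft[0, ])), 0)
  # out-of-range input refused
  bad <- ft
  bad$s_0 <- bad$s_0 + 5
  expect_error(predict(m, bad), "not normalized")
})

test_that("models round-trip through the JSON archive", {
  ft <- random_features(60, seed = 11, signal = 0.3)
  m <- train_classifier(build_model(fast_config(epochs = 3L)), ft, NULL)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  p1 <- predict(m, ft)
  p2 <- predict(m2, ft)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
})

test_that("AUC matches hand counts, pROC, and is monotone-invariant", {
  # 4-point toy set: concordant-pair enumeration gives 0.75
  scores <- c(0.9, 0.8, 0.7, 0.1)
  labels <- c(1, 0, 1, 0)
  expect_equal(roc_auc(scores, labels), 0.75)

  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)

  # chance level for independent scores
  set.seed(12)
  s <- runif(4000)
  l <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.03)

  # invariance under strictly monotone transforms
  expect_equal(roc_auc(qlogis(s / 2 + 0.25), l), roc_auc(s, l))

  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  set.seed(13)
  s2 <- rnorm(300)
  l2 <- rbinom(300, 1, plogis(s2))
  expect_equal(
    roc_auc(s2, l2),
    as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE, direction = "<"))),
    tolerance = 1e-10
  )
  expect_error(roc_auc(s2, rep(1, 300)), class = "surfcomp_domain_error")
})

test_that("confusion matrices are fractions that sum to one", {
  preds <- tibble::tibble(
    score = c(0.9, 0.7, 0.45, 0.3, 0.2, 0.05),
    truth = c(1, 1, 0, 1, 0, 0),
    pair_class = c("HH", "HH", "HP", "HP", "CC", "CC")
  )
  class(preds) <- c("prediction_set", class(preds))

  cm <- apply_threshold(preds, 0.38)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 1)
  # hand count at 0.38: scores >= 0.38 are {.9,.7,.45}; truths {1,1,0}
  expect_equal(cm$tp, 2 / 6)
  expect_equal(cm$fp, 1 / 6)
  expect_equal(cm$fn, 1 / 6)
  expect_equal(cm$tn, 2 / 6)

  # threshold 0: everything positive
  cm0 <- apply_threshold(preds, 0)
  expect_equal(cm0$tn + cm0$fn, 0)
  # threshold 1 with no score at 1: everything negative
  cm1 <- apply_threshold(preds, 1)
  expect_equal(cm1$tp + cm1$fp, 0)

  # per-class thresholds route by class; missing class falls back
  expect_warning(
    cmc <- apply_threshold(preds, c(HH = 0.8, HP = 0.4), fallback = 0.38),
    "CC"
  )
  expect_equal(cmc$tp + cmc$fp + cmc$tn + cmc$fn, 1)
})

test_that("roc_curve traces the staircase from (0,0) to (1,1)", {
  rc <- roc_curve(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
})
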