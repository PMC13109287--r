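# Mutual information, stratified AUC, PCA, class thresholds, ablation.

test_that("MI estimator reproduces closed forms", {
  set.seed(1)
  n <- 10000
  y <- rbinom(n, 1, 0.5)
  # fully informative feature against a balanced binary target: 1 bit
  expect_lt(abs(mutual_information(as.numeric(y), y) - 1.0), 0.01)
  # independent feature: near zero
  expect_lt(mutual_information(runif(n), y), 0.02)
  # binary channel with 10% flips: 1 - H(0.1) = 0.531 bits
  flip <- rbinom(n, 1, 0.1)
  x <- ifelse(flip == 1, 1 - y, y)
  h01 <- -(0.1 * log2(0.1) + 0.9 * log2(0.9))
  expect_lt(abs(mutual_information(as.numeric(x), y) - (1 - h01)), 0.02)
})

test_that("MI is symmetric, non-negative, and self-MI equals bin entropy", {
  set.seed(2)
  n <- 2000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, 0.5 + 0.2 * x)
  expect_equal(
    mutual_information(as.numeric(x), y),
    mutual_information(as.numeric(y), x),
    tolerance = 1e-12
  )
  expect_gte(mutual_information(runif(n), rbinom(n, 1, 0.5)), 0)

  # MI of a feature with its own discretization = entropy of the bins
  x2 <- rnorm(n)
  bins <- 8
  brks <- unique(quantile(x2, seq(0, 1, length.out = bins + 1), names = FALSE))
  xb <- cut(x2, brks, include.lowest = TRUE, labels = FALSE)
  p <- table(xb) / n
  expect_equal(
    mutual_information(x2, xb, bins = bins),
    -sum(p * log2(p)),
    tolerance = 1e-10
  )

  expect_warning(mi0 <- mutual_information(rep(1, 100), rbinom(100, 1, 0.5)), "constant")
  expect_equal(mi0, 0)
  expect_error(mutual_information(1:100, rep(1, 100)), class = "surfcomp_domain_error")
})

test_that("MI ranking finds planted informative features", {
  set.seed(3)
  n <- 800
  y <- rep(c(1L, 0L), n / 2)
  ft <- tibble::tibble(label = ifelse(y == 1, "core", "decoy"))
  for (k in c("s", "e", "h")) {
    for (j in 0:9) ft[[paste0(k, "_", j)]] <- runif(n)
  }
  ft$s_0 <- y + rnorm(n, sd = 0.3) # strongly informative
  ft$h_0 <- ft$s_0 # duplicated feature
  scores <- plogis(3 * (ft$s_0 - 0.5)) # NN-like score correlated with s_0
  mi <- mi_ranking(ft, y, scores)
  expect_equal(mi$rank_true[mi$feature == "s_0"], 1)
  expect_equal(
    mi$mi_true[mi$feature == "s_0"],
    mi$mi_true[mi$feature == "h_0"]
  ) # identical features -> identical MI
  # pure-noise features carry far less information than the planted one
  expect_lt(
    mi$mi_true[mi$feature == "e_5"],
    0.2 * mi$mi_true[mi$feature == "s_0"]
  )
  expect_true(all(c("mi_nn", "rank_nn") %in% names(mi)))
  expect_equal(mi$rank_nn[mi$feature == "s_0"], 1)
})

test_that("stratified AUC matches hand counts and conventions", {
  # identical distributions -> 0.5
  v <- rep(c(1, 2, 3, 4), 2)
  a <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(stratified_auc(v, a, !a), 0.5)
  # disjoint supports, group A lower (more complementary) -> 1
  expect_equal(stratified_auc(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE),
    c(FALSE, FALSE, TRUE, TRUE)),
  1.0)
  # toy 2+2 concordant-pair count: A = {1, 5}, B = {2, 6}
  # pairs (a<b): (1,2) (1,6) (5,6) = 3 of 4 -> 0.75
  expect_equal(
    stratified_auc(c(1, 5, 2, 6), c(TRUE, TRUE, FALSE, FALSE),
      c(FALSE, FALSE, TRUE, TRUE)),
    0.75
  )
  # direction flips for high-is-positive scores
  expect_equal(
    stratified_auc(c(9, 10, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
      c(FALSE, FALSE, TRUE, TRUE),
      direction = "high"
    ),
    1.0
  )
  expect_error(stratified_auc(v, rep(FALSE, 8), a), class = "surfcomp_domain_error")
})

test_that("PCA explained variance behaves on isotropic and planted data", {
  set.seed(4)
  # isotropic noise: EVR ~ 1/30 each
  X <- matrix(rnorm(3000 * 30), 3000, 30)
  rep_iso <- pca_evr(X)
  expect_equal(sum(rep_iso$evr$evr), 1, tolerance = 1e-12)
  expect_true(all(abs(rep_iso$evr$evr - 1 / 30) < 0.01))
  expect_true(all(diff(rep_iso$evr$eigenvalue) <= 1e-12))
  expect_true(all(diff(rep_iso$evr$cumulative) >= 0))

  # one dominant planted direction with uniform loading magnitudes (the
  # PCA standardizes columns, so the factor must load on all of them)
  v <- sample(c(-1, 1), 30, replace = TRUE) / sqrt(30)
  z <- rnorm(2000, sd = 5)
  Xp <- z %*% t(v) + matrix(rnorm(2000 * 30, sd = 0.5), 2000, 30)
  rep_p <- pca_evr(Xp)
  expect_gt(rep_p$evr$evr[1], 0.5)
  cosine <- abs(sum(rep_p$loadings[, 1] * v))
  expect_gt(cosine, 0.9)
  expect_equal(rep_p$n_selected, 1)
  # loadings columns are orthonormal
  G <- crossprod(rep_p$loadings[, 1:5])
  expect_equal(G, diag(5), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(pca_evr(X[1:10, ]), "more observations")
  Xc <- X
  Xc[, 3] <- 1
  expect_warning(pca_evr(Xc), "constant")
})

test_that("class thresholds maximize F1 per class with deterministic ties", {
  # toy set solved by enumeration: HH scores favor a low threshold
  preds <- tibble::tibble(
    score = c(0.2, 0.3, 0.9, 0.1, 0.6, 0.7),
    truth = c(1, 1, 1, 0, 0, 1),
    pair_class = c("HH", "HH", "HH", "HH", "PP", "PP")
  )
  class(preds) <- c("prediction_set", class(preds))
  rep_t <- class_thresholds(preds, universal = 0.38)
  hh <- rep_t$by_class[rep_t$by_class$pair_class == "HH", ]
  # exhaustive search oracle for class HH
  grid <- seq(0, 1, by = 0.01)
  f1 <- function(t) {
    p <- as.integer(preds$score[1:4] >= t)
    y <- preds$truth[1:4]
    tp <- sum(p & y)
    if (tp == 0) 0 else 2 * tp / (2 * tp + sum(p & !y) + sum(!p & y))
  }
  best <- max(vapply(grid, f1, numeric(1)))
  expect_equal(hh$f1_class, best)
  # tie broken toward the lower threshold
  expect_equal(hh$threshold, grid[which.max(vapply(grid, f1, numeric(1)))])
  # per-class optimum is never below the universal threshold's F1
  expect_true(all(rep_t$by_class$f1_class >= rep_t$by_class$f1_universal - 1e-12))
  # both confusion matrices are fraction tables summing to 1
  expect_equal(sum(rep_t$confusion_universal[1, 1:4]), 1)
  expect_equal(sum(rep_t$confusion_class[1, 1:4]), 1)
})

test_that("planted per-class score shifts are recovered by class thresholds", {
  set.seed(5)
  classes <- c("HH", "HP", "PP", "HC", "PC", "CC")
  shift <- setNames(seq(-0.15, 0.25, length.out = 6), classes)
  rows <- lapply(classes, function(cl) {
    n <- 120
    y <- rbinom(n, 1, 0.5)
    tibble::tibble(
      score = pmin(pmax(0.35 + shift[cl] + 0.25 * y + rnorm(n, sd = 0.12), 0), 1),
      truth = y, pair_class = cl
    )
  })
  preds <- dplyr::bind_rows(rows)
  class(preds) <- c("prediction_set", class(preds))
  rep_t <- class_thresholds(preds, universal = 0.38)
  expect_true(all(rep_t$by_class$f1_class >= rep_t$by_class$f1_universal - 1e-12))
  # recovered thresholds increase with the planted shift
  expect_gt(
    cor(rep_t$by_class$threshold, shift[rep_t$by_class$pair_class]),
    0.8
  )
})

test_that("single-label classes fall back to the universal threshold", {
  preds <- tibble::tibble(
    score = c(0.8, 0.9, 0.2, 0.4),
    truth = c(1, 1, 1, 0),
    pair_class = c("CC", "CC", "HH", "HH")
  )
  class(preds) <- c("prediction_set", class(preds))
  expect_warning(rep_t <- class_thresholds(preds), "one label")
  cc <- rep_t$by_class[rep_t$by_class$pair_class == "CC", ]
  expect_equal(cc$threshold, 0.38)
  expect_true(is.na(cc$auc))
})

test_that("a single ablation repetition is reproducible", {
  set.seed(6)
  n <- 200
  y <- rep(c(1L, 0L), n / 2)
  ft <- tibble::tibble(label = ifelse(y == 1, "core", "decoy"))
  for (k in c("s", "e", "h")) {
    for (j in 0:9) ft[[paste0(k, "_", j)]] <- runif(n) + 0.4 * y * (k == "s")
  }
  cfg <- classifier_config(
    filters = c(4L, 6L), dense = c(8L, 1L),
    epochs = 8L, patience = 3L, batch_size = 32L
  )
  a1 <- ablation_experiment(ft,
    subsets = list(s = "s", seh = c("s", "e", "h")),
    repetitions = 1, seed = 4, config = cfg
  )
  a2 <- ablation_experiment(ft,
    subsets = list(s = "s", seh = c("s", "e", "h")),
    repetitions = 1, seed = 4, config = cfg
  )
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 2)
  expect_true(all(a1$accuracy >= 0 & a1$accuracy <= 1))
})

test_that("feature correlations report Pearson r with exact p-values", {
  set.seed(7)
  n <- 200
  comp <- tibble::tibble(
    shape = rnorm(n),
    electrostatic = rnorm(n),
    hydropathy = rnorm(n)
  )
  comp$hydropathy <- comp$hydropathy + 0.5 * comp$shape
  fc <- feature_correlations(comp)
  expect_equal(nrow(fc), 3)
  ct <- cor.test(comp$shape, comp$hydropathy)
  row <- fc[fc$var1 == "shape" & fc$var2 == "hydropathy", ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p_value, ct$p.value)
})
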