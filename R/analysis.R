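# Interpretability pipeline: mutual-information ranking, distribution
# stratification, feature-subset ablation, PCA explained variance, and
# residue-class-specific decision thresholds.

#' Mutual information between a feature and a binary target
#'
#' Plug-in estimator of `MI(X,Y) = sum p(x,y) log2( p(x,y) / p(x) p(y) )`
#' after discretizing the feature into equal-frequency bins (default
#' `ceiling(sqrt(n / 5))`, capped at 32). Base-2 logarithm, so a fully
#' informative feature against a balanced binary target scores 1 bit.
#' Empty cells are skipped; the estimator is non-negative and symmetric.
#'
#' @param x Numeric feature values.
#' @param y Binary target (0/1, logical, or 2-level factor).
#' @param bins Number of bins; `NULL` for the default rule.
#' @return MI in bits.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (n != length(y)) abort("x and y must have equal length")
  if (n < 50) abort("need at least 50 observations for the MI estimate")
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2) {
    abort("target must have both classes", class = "surfcomp_domain_error")
  }
  if (length(unique(x)) == 1) {
    warn("constant feature: MI = 0")
    return(0)
  }
  if (is.null(bins)) bins <- min(32L, ceiling(sqrt(n / 5)))
  ux <- unique(x)
  if (length(ux) <= bins) {
    # discrete feature: its values are their own bins
    xb <- match(x, sort(ux))
  } else {
    brks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE))
    xb <- cut(x, breaks = brks, include.lowest = TRUE, labels = FALSE)
  }
  joint <- table(xb, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}

#' Mutual-information ranking of the feature space
#'
#' Ranks every feature column by its MI with the true core/decoy label and
#' with the classifier's prediction (binary at the universal threshold by
#' default, or the continuous scores with `nn_binary = FALSE`).
#'
#' @param features Feature tibble (normalized or raw; MI is invariant to
#'   monotone rescaling up to binning).
#' @param truth Binary true labels.
#' @param nn_scores Classifier scores for the same rows (optional).
#' @param threshold Universal threshold used to binarize `nn_scores`.
#' @param nn_binary Binarize the scores before computing MI (default TRUE).
#' @param bins Passed to [mutual_information()].
#' @return An `mi_report` tibble: `feature`, `kind`, `neighbor`, `mi_true`,
#'   `rank_true` and, when scores are given, `mi_nn`, `rank_nn`.
#' @export
mi_ranking <- function(features, truth, nn_scores = NULL, threshold = 0.38,
                       nn_binary = TRUE, bins = NULL) {
  fcols <- grep("^[seh]_[0-9]$", names(features), value = TRUE)
  if (length(fcols) == 0) abort("no feature columns found")
  out <- tibble::tibble(
    feature = fcols,
    kind = unname(FEATURE_KINDS[substr(fcols, 1, 1)]),
    neighbor = as.integer(sub("^[seh]_", "", fcols)),
    mi_true = unname(vapply(
      fcols, function(f) mutual_information(features[[f]], truth, bins = bins),
      numeric(1)
    ))
  )
  out$rank_true <- rank(-out$mi_true, ties.method = "min")
  if (!is.null(nn_scores)) {
    nn_y <- if (nn_binary) as.integer(nn_scores >= threshold) else nn_scores
    if (nn_binary && length(unique(nn_y)) < 2) {
      warn("all predictions on one side of the threshold; using continuous scores")
      nn_y <- nn_scores
    }
    if (nn_binary && length(unique(nn_y)) >= 2) {
      out$mi_nn <- unname(vapply(
        fcols, function(f) mutual_information(features[[f]], nn_y, bins = bins),
        numeric(1)
      ))
    } else {
      # continuous target: discretize the scores like a feature
      nb <- if (is.null(bins)) min(32L, ceiling(sqrt(length(nn_y) / 5))) else bins
      yb <- cut(nn_y,
        breaks = unique(quantile(nn_y, seq(0, 1, length.out = nb + 1), names = FALSE)),
        include.lowest = TRUE, labels = FALSE
      )
      out$mi_nn <- unname(vapply(fcols, function(f) {
        xb <- features[[f]]
        suppressWarnings(mutual_information(xb, yb > stats::median(yb), bins = bins))
      }, numeric(1)))
    }
    out$rank_nn <- rank(-out$mi_nn, ties.method = "min")
  }
  class(out) <- c("mi_report", class(out))
  out
}

#' ROC AUC separating two groups of a value distribution
#'
#' AUC of a scalar value as a score separating group A from group B. By
#' convention smaller values (higher complementarity) score as the
#' "positive" group A, i.e. the reported AUC is that of `-value` for
#' A-vs-B; use `direction = "high"` for values where larger means positive.
#'
#' @param values Numeric vector.
#' @param group_a,group_b Logical masks (or index vectors) of the two
#'   groups; must be non-empty and disjoint.
#' @param direction `"low"` (default: low values indicate group A) or
#'   `"high"`.
#' @return AUC in `[0, 1]`.
#' @export
stratified_auc <- function(values, group_a, group_b, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (!is.logical(group_a)) group_a <- seq_along(values) %in% group_a
  if (!is.logical(group_b)) group_b <- seq_along(values) %in% group_b
  if (!any(group_a) || !any(group_b)) {
    abort("both groups must be non-empty", class = "surfcomp_domain_error")
  }
  if (any(group_a & group_b)) abort("groups overlap")
  v <- c(values[group_a], values[group_b])
  lab <- c(rep(1L, sum(group_a)), rep(0L, sum(group_b)))
  s <- if (direction == "low") -v else v
  roc_auc(s, lab)
}

ALL_FEATURE_SUBSETS <- list(
  "s" = "s", "e" = "e", "h" = "h",
  "se" = c("s", "e"), "sh" = c("s", "h"), "eh" = c("e", "h"),
  "seh" = c("s", "e", "h")
)

#' Feature-subset ablation experiment
#'
#' Trains and tests the classifier repeatedly on every non-empty subset of
#' the three complementarity kinds, with an independent 70/15/15
#' train/validation/test split per repetition. Each run normalizes on its
#' training split, picks the accuracy-maximizing decision threshold on its
#' validation split (the analogue of the universal cut-off), and reports
#' test accuracy at that threshold.
#'
#' @param features Unnormalized feature tibble with a `label` column.
#' @param subsets Named list of feature-kind subsets (default: all 7).
#' @param repetitions Independent repetitions per subset (default 100; use
#'   fewer for desk-scale runs).
#' @param seed Master seed; repetition r uses a derived seed.
#' @param config Classifier config. The default is a reduced profile
#'   (8/16 filters, 32-unit dense layer, 30 epochs, batch 128) sized so
#'   that the 7 subsets x repetitions grid stays affordable on one core;
#'   the same architecture is used for every subset, so the comparison is
#'   like-for-like.
#' @return An `ablation_report` tibble: `subset`, `repetition`, `accuracy`,
#'   `auc`, `threshold`.
#' @export
ablation_experiment <- function(features,
                                subsets = ALL_FEATURE_SUBSETS,
                                repetitions = 100L, seed = 1L,
                                config = classifier_config(
                                  filters = c(8L, 16L), dense = c(32L, 1L),
                                  epochs = 30L, patience = 5L,
                                  batch_size = 128L
                                )) {
  stopifnot("label" %in% names(features))
  n <- nrow(features)
  rows <- list()
  for (rep_i in seq_len(repetitions)) {
    split <- with_seed(derive_seed(seed, "split", rep_i), {
      ord <- sample.int(n)
      n_tr <- floor(0.70 * n)
      n_va <- floor(0.15 * n)
      list(
        train = ord[seq_len(n_tr)],
        val = ord[n_tr + seq_len(n_va)],
        test = ord[(n_tr + n_va + 1L):n]
      )
    })
    tr_raw <- features[split$train, ]
    tr <- normalize_features(tr_raw)
    stats <- attr(tr, "norm_stats")
    va <- normalize_features(features[split$val, ], stats)
    te <- normalize_features(features[split$test, ], stats)
    for (sname in names(subsets)) {
      kinds <- subsets[[sname]]
      cfg <- config
      cfg$seed <- derive_seed(seed, "net", rep_i, sname)
      model <- build_model(cfg, input_shape = c(length(kinds), 10L))
      model <- train_classifier(
        model,
        as_model_input(tr, kinds),
        as_model_input(va, kinds)
      )
      pv <- predict(model, as_model_input(va, kinds))
      grid_thr <- seq(0.01, 0.99, by = 0.01)
      acc_va <- vapply(
        grid_thr,
        function(t) mean((pv$score >= t) == (pv$truth == 1)),
        numeric(1)
      )
      thr <- grid_thr[which.max(acc_va)]
      pt <- predict(model, as_model_input(te, kinds))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset = sname, repetition = rep_i,
        accuracy = mean((pt$score >= thr) == (pt$truth == 1)),
        auc = roc_auc(pt$score, pt$truth),
        threshold = thr
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ablation_report", class(out))
  out
}

#' PCA of the feature space with explained variance ratios
#'
#' Standardizes the 30 feature columns (zero mean, unit variance), performs
#' an eigendecomposition of the correlation structure and reports the
#' explained variance ratio `EVR_i = lambda_i / sum_j lambda_j` per
#' component, the cumulative EVR, the loadings, and the number of
#' components selected by the scree rule (components up to and including
#' the largest consecutive eigenvalue drop, capped at 10).
#'
#' @param features Feature tibble (or plain numeric matrix).
#' @param scree_cap Maximum selected components (default 10).
#' @return A `pca_report` list: `evr` tibble (`component`, `eigenvalue`,
#'   `evr`, `cumulative`), `loadings` matrix (features x components),
#'   `n_selected`.
#' @export
pca_evr <- function(features, scree_cap = 10L) {
  X <- if (is.data.frame(features)) {
    fcols <- grep("^[seh]_[0-9]$", names(features), value = TRUE)
    if (length(fcols) == 0) abort("no feature columns found")
    as.matrix(features[fcols])
  } else {
    as.matrix(features)
  }
  if (nrow(X) <= ncol(X)) abort("need more observations than features")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn("constant feature column(s) dropped from the PCA")
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  lambda <- pc$sdev^2
  evr <- lambda / sum(lambda)
  drops <- -diff(lambda)
  n_sel <- min(which.max(drops), scree_cap)
  out <- list(
    evr = tibble::tibble(
      component = seq_along(lambda), eigenvalue = lambda,
      evr = evr, cumulative = cumsum(evr)
    ),
    loadings = pc$rotation,
    n_selected = as.integer(n_sel)
  )
  class(out) <- "pca_report"
  out
}

#' @export
print.pca_report <- function(x, ...) {
  cat(
    "<pca_report>", nrow(x$loadings), "features;",
    x$n_selected, "components selected by the scree rule; EVR1 =",
    round(x$evr$evr[1], 3), "\n"
  )
  invisible(x)
}

#' @rdname pca_evr
#' @param x A `pca_report`.
#' @param ... Unused.
#' @export
tidy.pca_report <- function(x, ...) x$evr

f1_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' Residue-class-specific decision thresholds
#'
#' For each chemical pair class, grid-searches thresholds (step 0.01 in
#' `[0, 1]`) maximizing the F1 score on that class (ties broken toward the
#' lower threshold, favoring sensitivity) and reports the class ROC AUC,
#' the optimal threshold, and F1 under the universal vs the class
#' threshold, plus the two global confusion matrices. A class with a single
#' label falls back to the universal threshold.
#'
#' @param predictions A `prediction_set` with `score`, `truth`,
#'   `pair_class`.
#' @param universal Universal threshold (default 0.38).
#' @param step Grid step (default 0.01).
#' @return A `threshold_report` list: `by_class` tibble (`pair_class`,
#'   `n`, `auc`, `threshold`, `f1_universal`, `f1_class`),
#'   `confusion_universal`, `confusion_class` (fraction tibbles), and the
#'   threshold map.
#' @export
class_thresholds <- function(predictions, universal = 0.38, step = 0.01) {
  stopifnot(all(c("score", "truth", "pair_class") %in% names(predictions)))
  grid_thr <- seq(0, 1, by = step)
  classes <- intersect(PAIR_CLASSES, unique(predictions$pair_class))
  rows <- list()
  thr_map <- c()
  for (cl in classes) {
    sub <- predictions[predictions$pair_class == cl, ]
    if (length(unique(sub$truth)) < 2) {
      warn(paste0("class ", cl, " has one label only; universal threshold used"))
      thr_map[cl] <- universal
      rows[[cl]] <- tibble::tibble(
        pair_class = cl, n = nrow(sub), auc = NA_real_, threshold = universal,
        f1_universal = f1_score(as.integer(sub$score >= universal), sub$truth),
        f1_class = f1_score(as.integer(sub$score >= universal), sub$truth)
      )
      next
    }
    f1s <- vapply(
      grid_thr,
      function(t) f1_score(as.integer(sub$score >= t), sub$truth),
      numeric(1)
    )
    best <- grid_thr[which.max(f1s)] # which.max takes the first = lowest
    thr_map[cl] <- best
    rows[[cl]] <- tibble::tibble(
      pair_class = cl, n = nrow(sub),
      auc = roc_auc(sub$score, sub$truth),
      threshold = best,
      f1_universal = f1_score(as.integer(sub$score >= universal), sub$truth),
      f1_class = max(f1s)
    )
  }
  out <- list(
    by_class = dplyr::bind_rows(rows),
    confusion_universal = apply_threshold(predictions, universal),
    confusion_class = apply_threshold(predictions, as.list(thr_map), fallback = universal),
    thresholds = thr_map,
    universal = universal
  )
  class(out) <- "threshold_report"
  out
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report> universal =", x$universal, "\n")
  print(x$by_class)
  invisible(x)
}

#' @rdname class_thresholds
#' @param x A `threshold_report`.
#' @param ... Unused.
#' @export
tidy.threshold_report <- function(x, ...) x$by_class

#' Pairwise Pearson correlations of the direct complementarities
#'
#' Reporting utility: correlations (with two-sided p-values from the exact
#' t transform) between the shape, electrostatic and hydropathy
#' complementarity of each pair.
#'
#' @param complementarities Tibble with columns `shape`, `electrostatic`,
#'   `hydropathy` (from [pair_complementarities()]).
#' @return Tibble `var1`, `var2`, `r`, `p_value`.
#' @export
feature_correlations <- function(complementarities) {
  vars <- c("shape", "electrostatic", "hydropathy")
  stopifnot(all(vars %in% names(complementarities)))
  combos <- utils::combn(vars, 2)
  dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(i) {
    ct <- stats::cor.test(
      complementarities[[combos[1, i]]],
      complementarities[[combos[2, i]]]
    )
    tibble::tibble(
      var1 = combos[1, i], var2 = combos[2, i],
      r = unname(ct$estimate), p_value = ct$p.value
    )
  }))
}
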