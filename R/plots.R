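# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_boxplot
#'   geom_point geom_density geom_abline facet_wrap labs theme_minimal
#'   position_dodge scale_x_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot annular interface composition
#'
#' Class frequencies (H/P/C) per 1 A ring of distance from the interface
#' center.
#'
#' @param object An `annular_composition` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annular_composition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::all_of(c("f_H", "f_P", "f_C")),
    names_to = "class", values_to = "frequency"
  )
  long$class <- sub("^f_", "", long$class)
  long$mid <- (long$r_lo + long$r_hi) / 2
  ggplot(
    long[!is.na(long$frequency), ],
    aes(x = .data$mid, y = .data$frequency, colour = .data$class)
  ) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "distance from interface center (Å)",
      y = "residue class frequency", colour = "class"
    ) +
    theme_minimal()
}

#' Plot a mutual-information ranking
#'
#' MI per feature against the true labels and (when present) against the
#' classifier prediction.
#'
#' @param object An `mi_report` from [mi_ranking()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  value_cols <- intersect(c("mi_true", "mi_nn"), names(df))
  long <- tidyr::pivot_longer(df, dplyr::all_of(value_cols),
    names_to = "target", values_to = "mi"
  )
  long$target <- c(mi_true = "true labels", mi_nn = "NN prediction")[long$target]
  long$feature <- factor(long$feature, levels = df$feature[order(df$mi_true)])
  ggplot(long, aes(x = .data$mi, y = .data$feature, fill = .data$kind)) +
    geom_col() +
    facet_wrap(~target) +
    labs(x = "mutual information (bits)", y = NULL, fill = "complementarity") +
    theme_minimal()
}

#' Plot a PCA scree curve
#'
#' Explained variance ratio per component with the cumulative curve.
#'
#' @param object A `pca_report` from [pca_evr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_report <- function(object, ...) {
  df <- object$evr
  ggplot(df, aes(x = .data$component)) +
    geom_col(aes(y = .data$evr), fill = "grey70") +
    geom_line(aes(y = .data$cumulative), colour = "steelblue") +
    geom_point(aes(y = .data$cumulative), colour = "steelblue", size = 0.8) +
    scale_x_continuous(breaks = pretty(df$component)) +
    labs(x = "principal component", y = "explained variance ratio") +
    theme_minimal()
}

#' Plot ablation accuracy distributions
#'
#' Test accuracy per feature subset over the repetitions.
#'
#' @param object An `ablation_report` from [ablation_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ablation_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  med <- tapply(df$accuracy, df$subset, stats::median)
  df$subset <- factor(df$subset, levels = names(sort(med)))
  ggplot(df, aes(x = .data$subset, y = .data$accuracy)) +
    geom_boxplot(fill = "grey85") +
    labs(x = "feature subset", y = "test accuracy") +
    theme_minimal()
}

#' Plot per-class F1 under universal vs class thresholds
#'
#' @param object A `threshold_report` from [class_thresholds()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_class,
    dplyr::all_of(c("f1_universal", "f1_class")),
    names_to = "cutoff", values_to = "f1"
  )
  long$cutoff <- c(
    f1_universal = paste0("universal (", object$universal, ")"),
    f1_class = "class-specific"
  )[long$cutoff]
  ggplot(long, aes(x = .data$pair_class, y = .data$f1, fill = .data$cutoff)) +
    geom_col(position = position_dodge()) +
    labs(x = "pair class", y = "F1 score", fill = NULL) +
    theme_minimal()
}

#' Plot score distributions of a prediction set
#'
#' Score densities split by the true label.
#'
#' @param object A `prediction_set` with a `truth` column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prediction_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$truth == 1, "core interacting", "decoy")
  ggplot(df, aes(x = .data$score, fill = .data$label)) +
    geom_density(alpha = 0.5) +
    labs(x = "NN score", y = "density", fill = NULL) +
    theme_minimal()
}

#' Plot an ROC curve
#'
#' @param roc Tibble from [roc_curve()].
#' @param auc Optional AUC annotation.
#' @return A ggplot.
#' @export
plot_roc <- function(roc, auc = NULL) {
  p <- ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line(colour = "steelblue") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(
      x = "false positive rate", y = "true positive rate",
      title = if (!is.null(auc)) sprintf("ROC (AUC = %.3f)", auc)
    ) +
    theme_minimal()
  p
}
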