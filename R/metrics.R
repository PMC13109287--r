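# ROC analysis and threshold application for prediction sets.

#' ROC curve points
#'
#' True/false positive rates over all score thresholds (one step per
#' distinct score), higher scores predicting the positive class.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) true labels.
#' @return Tibble with `threshold`, `tpr`, `fpr`, ordered from the most
#'   permissive to the strictest threshold.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(unique(labels)) < 2) {
    abort("ROC needs both classes present", class = "surfcomp_domain_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, numeric(1))
  tibble::tibble(
    threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr)
  )
}

#' Area under the ROC curve
#'
#' Computed by rank averaging (the Mann-Whitney statistic), equivalent to
#' the trapezoidal rule over all thresholds with tied scores handled by
#' mid-ranks. Invariant under strictly monotone transforms of the scores.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC needs both classes present", class = "surfcomp_domain_error")
  }
  r <- rank(scores) # mid-ranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion matrix at a decision threshold
#'
#' Applies a universal threshold, or a per-class map routing each pair by
#' its chemical pair class, and reports the four cells as fractions of all
#' pairs (they sum to 1). A score is called positive when it is `>=` the
#' threshold.
#'
#' @param predictions A `prediction_set` (needs `score`, `truth`, and
#'   `pair_class` for per-class thresholds).
#' @param threshold Scalar threshold (default 0.38) or a named vector /
#'   list mapping pair classes (`"HH"`, `"HP"`, ...) to thresholds. Classes
#'   missing from the map fall back to `fallback` with a warning.
#' @param fallback Universal fallback threshold for unmapped classes.
#' @return Tibble with one row: `tp`, `fp`, `tn`, `fn` (fractions),
#'   `accuracy`, `f1`, `threshold_kind`.
#' @export
apply_threshold <- function(predictions, threshold = 0.38, fallback = 0.38) {
  stopifnot(all(c("score", "truth") %in% names(predictions)))
  scores <- predictions$score
  truth <- as.integer(predictions$truth)
  if (length(threshold) > 1 || !is.null(names(threshold))) {
    if (!"pair_class" %in% names(predictions)) {
      abort("per-class thresholds need a pair_class column")
    }
    thr_map <- unlist(threshold)
    cls <- predictions$pair_class
    missing <- setdiff(unique(cls), names(thr_map))
    if (length(missing) > 0) {
      warn(paste0(
        "no threshold for class(es) ", paste(missing, collapse = ", "),
        "; using fallback ", fallback
      ))
    }
    thr <- unname(thr_map[cls])
    thr[is.na(thr)] <- fallback
    kind <- "per-class"
  } else {
    thr <- rep(threshold, length(scores))
    kind <- "universal"
  }
  pred <- as.integer(scores >= thr)
  n <- length(pred)
  tp <- sum(pred == 1 & truth == 1) / n
  fp <- sum(pred == 1 & truth == 0) / n
  tn <- sum(pred == 0 & truth == 0) / n
  fn <- sum(pred == 0 & truth == 1) / n
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = tp + tn, f1 = f1, threshold_kind = kind
  )
}
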