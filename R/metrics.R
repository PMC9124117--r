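#' Confusion counts for binary graft-survival predictions
#'
#' Tabulates predictions against truth with class 1 ("survive") as the
#' positive class: `tp` survivals predicted as survivals, `tn` failures
#' predicted as failures, `fp` failures predicted as survivals, `fn`
#' survivals predicted as failures. Counts always sum to the number of
#' evaluated records.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @param positive The positive-class value (default 1).
#' @return A one-row tibble `(tp, tn, fp, fn)` of class `confusion_counts`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.",
          class = "graftann_data_error")
  }
  if (!length(y_true)) {
    abort("Cannot tabulate an empty prediction set.",
          class = "graftann_data_error")
  }
  t_pos <- y_true == positive
  p_pos <- y_pred == positive
  out <- tibble(
    tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Classification accuracy
#'
#' `(tp + tn) / (tp + fp + tn + fn)`.
#'
#' @param counts A [confusion_counts()] row.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) {
    abort("Confusion counts are all zero.", class = "graftann_data_error")
  }
  (counts$tp + counts$tn) / total
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(paste0(what, " denominator is zero; returning 0 by convention."))
    return(0)
  }
  num / den
}

#' Precision, recall and F-measure
#'
#' Precision `tp / (tp + fp)`, recall `tp / (tp + fn)`, and their harmonic
#' mean `F = 2PR / (P + R)`. A zero denominator returns 0 with a warning
#' (this arises only for degenerate predictions, e.g. nothing predicted
#' positive). `variant_formula = TRUE` in `precision()` reproduces, for audit
#' purposes only, a variant formula `tp / (tn + fp)` that appears in some
#' reports but contradicts the standard definition; it is never used by the
#' pipeline.
#'
#' @param counts A [confusion_counts()] row.
#' @param variant_formula Audit flag for the non-standard precision variant.
#' @return A value in \[0, 1\] (the audit variant can exceed 1).
#' @export
precision <- function(counts, variant_formula = FALSE) {
  if (variant_formula) {
    return(safe_ratio(counts$tp, counts$tn + counts$fp, "Precision"))
  }
  safe_ratio(counts$tp, counts$tp + counts$fp, "Precision")
}

#' @rdname precision
#' @export
recall <- function(counts) {
  safe_ratio(counts$tp, counts$tp + counts$fn, "Recall")
}

#' @rdname precision
#' @export
f_measure <- function(counts) {
  p <- precision(counts)
  r <- recall(counts)
  if (p + r == 0) {
    warn("F-measure denominator is zero; returning 0 by convention.")
    return(0)
  }
  2 * p * r / (p + r)
}

#' Root-mean-square and mean absolute error of scored predictions
#'
#' Standard definitions against the 0/1 labels:
#' `rmse = sqrt(mean((score - label)^2))`, `mae = mean(|score - label|)`.
#' Scores are typically the predicted survival probabilities; passing hard
#' 0/1 predictions gives the hard-label variants. `rmse >= mae` always.
#'
#' @param y_true Binary (0/1) labels.
#' @param scores Numeric scores of equal length.
#' @return A non-negative error value.
#' @export
rmse <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    abort("`y_true` and `scores` must have equal length.",
          class = "graftann_data_error")
  }
  sqrt(mean((scores - y_true)^2))
}

#' @rdname rmse
#' @export
mae <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    abort("`y_true` and `scores` must have equal length.",
          class = "graftann_data_error")
  }
  mean(abs(scores - y_true))
}

#' Full performance report
#'
#' Computes the six reported measures — accuracy, precision, recall,
#' F-measure, RMSE and MAE — for a set of predictions. By default the error
#' measures are computed on the predicted probabilities (`scores`); set
#' `error_on = "class"` (or omit `scores`) to compute them on the hard 0/1
#' predictions.
#'
#' @param y_true Binary truth vector.
#' @param y_pred Binary predictions.
#' @param scores Optional predicted probabilities.
#' @param error_on `"prob"` (default when `scores` given) or `"class"`.
#' @param positive Positive-class value (default 1, "survive").
#' @return A one-row tibble of class `metrics_report` with the confusion
#'   counts and the six measures.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL,
                           error_on = c("prob", "class"), positive = 1) {
  error_on <- match.arg(error_on)
  counts <- confusion_counts(y_true, y_pred, positive = positive)
  err_scores <- if (error_on == "prob" && !is.null(scores)) scores else
    as.numeric(y_pred == positive)
  y01 <- as.numeric(y_true == positive)
  out <- dplyr::bind_cols(
    counts,
    tibble(
      accuracy = accuracy(counts),
      precision = precision(counts),
      recall = recall(counts),
      f_measure = f_measure(counts),
      rmse = rmse(y01, err_scores),
      mae = mae(y01, err_scores)
    )
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Graft-survival prediction performance\n")
  cat(sprintf("  confusion: tp=%d tn=%d fp=%d fn=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  for (m in c("accuracy", "precision", "recall", "f_measure")) {
    cat(sprintf("  %-10s %6.2f%%\n", m, 100 * x[[m]]))
  }
  cat(sprintf("  %-10s %6.4f\n  %-10s %6.4f\n", "rmse", x$rmse, "mae", x$mae))
  invisible(x)
}
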