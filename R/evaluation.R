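#' Confusion matrix for the 4-class rhythm task
#'
#' Rows are true classes, columns predicted, in the fixed order AFIB, GSVT,
#' SB, SR.
#'
#' @param truth,predicted vectors of class codes (0..3) or labels, equal
#'   length.
#' @return 4x4 integer matrix of class `rhythm_confusion` with dimnames.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1, 2, 3), c(0, 1, 1, 2, 3))
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort_param("`truth` and `predicted` must have equal length")
  }
  t_codes <- as_class_code(truth)
  p_codes <- as_class_code(predicted)
  cls <- names(rhythm_classes())
  cm <- matrix(0L, 4, 4, dimnames = list(true = cls, predicted = cls))
  for (i in seq_along(t_codes)) {
    cm[t_codes[i] + 1L, p_codes[i] + 1L] <- cm[t_codes[i] + 1L, p_codes[i] + 1L] + 1L
  }
  structure(cm, class = c("rhythm_confusion", "matrix", "array"))
}

#' One-vs-rest counts for a class
#'
#' @param cm a confusion matrix from [confusion_matrix()].
#' @param cls class label or code.
#' @return named vector `TP`, `FN`, `FP`, `TN`.
#' @export
ovr_counts <- function(cm, cls) {
  k <- as_class_code(cls) + 1L
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class one-vs-rest metrics
#'
#' Reduces the 4-class confusion matrix to binary counts per class and
#' applies the standard definitions, in percent:
#' accuracy (TP+TN)/total, sensitivity TP/(TP+FN), precision TP/(TP+FP),
#' specificity TN/(TN+FP), and F1 as the harmonic mean of precision and
#' sensitivity. A class with no support yields `NaN` sensitivity with a
#' warning rather than a silent zero.
#'
#' @param cm a confusion matrix from [confusion_matrix()].
#' @return tibble, one row per class: `class`, `sensitivity`, `precision`,
#'   `specificity`, `f1`, `accuracy` (percent, full precision).
#' @export
class_metrics <- function(cm) {
  if (sum(cm) == 0) abort_param("empty confusion matrix")
  rows <- lapply(names(rhythm_classes()), function(cl) {
    ct <- ovr_counts(cm, cl)
    tp <- ct["TP"]; fn <- ct["FN"]; fp <- ct["FP"]; tn <- ct["TN"]
    if (tp + fn == 0) {
      rlang::warn(sprintf("class %s has no support; sensitivity undefined", cl))
    }
    sens <- unname(tp / (tp + fn))
    prec <- unname(tp / (tp + fp))
    spec <- unname(tn / (tn + fp))
    f1 <- unname(2 * prec * sens / (prec + sens))
    acc <- unname((tp + tn) / sum(ct))
    tibble::tibble(class = cl, sensitivity = 100 * sens,
                   precision = 100 * prec, specificity = 100 * spec,
                   f1 = 100 * f1, accuracy = 100 * acc)
  })
  dplyr::bind_rows(rows)
}

#' Macro "Overall" row
#'
#' Unweighted arithmetic mean of each metric across the four per-class
#' rows — the aggregation rule of the study's result tables. (Note this
#' makes the overall accuracy a macro one-vs-rest accuracy, not the global
#' fraction correct.)
#'
#' @param per_class tibble of exactly 4 rows as produced by
#'   [class_metrics()].
#' @return one-row tibble with `class = "Overall"`.
#' @export
overall_row <- function(per_class) {
  if (nrow(per_class) != 4) abort_param("expected exactly 4 per-class rows")
  num <- dplyr::summarise(per_class, dplyr::across(dplyr::where(is.numeric),
                                                   mean))
  dplyr::bind_cols(tibble::tibble(class = "Overall"), num)
}

#' Full metrics report
#'
#' Per-class rows plus the macro Overall row, in the layout of the study's
#' tables (Sensitivity, Precision, Specificity, F1-Score, Accuracy).
#' Values are kept at full precision; set `digits` to round half-up for
#' presentation.
#'
#' @param cm a confusion matrix, or `truth`/`predicted` vectors via `...`.
#' @param digits optional presentation rounding (half-up).
#' @return tibble with 5 rows (4 classes + Overall).
#' @export
metrics_report <- function(cm, digits = NULL) {
  per_class <- class_metrics(cm)
  out <- dplyr::bind_rows(per_class, overall_row(per_class))
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ round_half_up(.x, digits)))
  }
  out
}

#' Evaluate a fitted model on a test set
#'
#' Runs inference (argmax over the 4 class probabilities, ties to the
#' lowest class index), assembles the confusion matrix and the metric
#' table.
#'
#' @param fit an `ecg_fit` or `ecg_network`.
#' @param x (leads x samples x n) array or list of records.
#' @param truth class codes or labels.
#' @param digits optional presentation rounding for the report.
#' @return list with `confusion` (matrix), `report` (tibble), `accuracy`
#'   (global fraction correct, percent), `predictions`.
#' @export
evaluate_model <- function(fit, x, truth, digits = NULL) {
  y <- as_class_code(truth)
  if (length(y) == 0) abort_param("empty test set")
  pred <- predict.ecg_fit(fit, x, type = "class")
  cm <- confusion_matrix(y, pred)
  list(confusion = cm,
       report = metrics_report(cm, digits = digits),
       accuracy = 100 * mean(pred == y),
       predictions = pred)
}

#' Plot a confusion matrix
#'
#' @param object a `rhythm_confusion` matrix.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rhythm_confusion
#' @export
autoplot.rhythm_confusion <- function(object, ...) {
  df <- as.data.frame.table(unclass(object), responseName = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(names(rhythm_classes()))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
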