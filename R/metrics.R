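#' Confusion matrix for binary classification
#'
#' Counts true/false positives/negatives with malignant (label 1) as the
#' positive class.
#'
#' @param y_true,y_pred integer vectors with entries in {0 = benign,
#'   1 = malignant}, equal length.
#' @return a `confusion_matrix`: list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("labels must be 0 (benign) or 1 (malignant)")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

cm_total <- function(cm) cm$TP + cm$FP + cm$TN + cm$FN

# Ratios with a zero denominator are genuinely undefined; they surface as
# NA (rendered "n/a" in reports), never as a silent 0.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' `accuracy` = (TP+TN)/N; `error_rate` = (FP+FN)/N = 1 - accuracy;
#' `recall` = TP/(TP+FN); `precision` = TP/(TP+FP); `f1_score` is the
#' harmonic mean of recall and precision, 2RP/(R+P). Any ratio with a zero
#' denominator returns `NA` rather than a silent 0.
#'
#' @param cm a `confusion_matrix`.
#' @return scalar in \[0, 1\], or `NA` when undefined.
#' @export
accuracy <- function(cm) safe_ratio(cm$TP + cm$TN, cm_total(cm))

#' @rdname accuracy
#' @export
error_rate <- function(cm) safe_ratio(cm$FP + cm$FN, cm_total(cm))

#' @rdname accuracy
#' @export
recall <- function(cm) safe_ratio(cm$TP, cm$TP + cm$FN)

#' @rdname accuracy
#' @export
precision <- function(cm) safe_ratio(cm$TP, cm$TP + cm$FP)

#' @rdname accuracy
#' @param recall_or_cm either a `confusion_matrix` or a recall value.
#' @param precision_value precision value, when the first argument is a
#'   recall.
#' @export
f1_score <- function(recall_or_cm, precision_value = NULL) {
  if (inherits(recall_or_cm, "confusion_matrix")) {
    r <- recall(recall_or_cm); p <- precision(recall_or_cm)
  } else {
    r <- recall_or_cm; p <- precision_value
    if (is.null(p)) stop("supply precision alongside recall")
  }
  if (is.na(r) || is.na(p)) return(NA_real_)
  if (r + p == 0) return(NA_real_)
  2 * r * p / (r + p)
}

#' Evaluate a trained network on a dataset
#'
#' Predicts every image, builds the confusion matrix, and returns one
#' tidy metrics row.
#'
#' @param spec a `cnn_spec`.
#' @param weights a `cnn_weights`.
#' @param dataset an `image_dataset`.
#' @param optimizer,batch_size,iterations,seed run descriptors copied into
#'   the row (for report CSVs).
#' @return one-row data.frame with columns `optimizer`, `batch_size`,
#'   `iterations`, `seed`, `accuracy`, `recall`, `precision`, `f1`,
#'   `error_rate`.
#' @export
evaluate_model <- function(spec, weights, dataset, optimizer = NA_character_,
                           batch_size = NA_integer_, iterations = NA_integer_,
                           seed = NA_integer_) {
  pred <- cnn_predict(spec, weights, dataset)
  cm <- confusion(dataset$meta$y, pred)
  data.frame(optimizer = optimizer, batch_size = batch_size,
             iterations = iterations, seed = seed,
             accuracy = accuracy(cm), recall = recall(cm),
             precision = precision(cm), f1 = f1_score(cm),
             error_rate = error_rate(cm), stringsAsFactors = FALSE)
}

#' Write a metrics report CSV
#'
#' Fixed schema: optimizer, batch_size, iterations, seed, accuracy,
#' recall, precision, f1, error_rate. Undefined metrics (`NA`) are
#' written as `"n/a"`.
#'
#' @param rows data.frame as returned by [evaluate_model()] (rbind-able).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  cols <- c("optimizer", "batch_size", "iterations", "seed", "accuracy",
            "recall", "precision", "f1", "error_rate")
  stopifnot(all(cols %in% names(rows)))
  utils::write.csv(rows[, cols], path, row.names = FALSE, na = "n/a")
  invisible(path)
}
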