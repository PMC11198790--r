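#' Multi-class confusion matrix
#'
#' Builds the `n x n` table of actual (rows) versus predicted (columns)
#' class counts. Labels are 1-based class indices in `1..n_classes`.
#'
#' @param y_true,y_pred Equal-length integer label vectors.
#' @param n_classes Number of classes.
#' @param class_names Optional class names (length `n_classes`).
#' @return A `confusion_matrix` (integer matrix with dimnames).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (any(y_true < 1L | y_true > n_classes) ||
      any(y_pred < 1L | y_pred > n_classes)) {
    stop("labels must lie in 1..n_classes")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = class_names, predicted = class_names))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Precision, recall, F1 and overall accuracy from a confusion matrix
#'
#' Per class (one-vs-rest): precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, F1 the harmonic mean `2PR / (P + R)`; any metric with
#' a zero denominator is defined as 0. Overall accuracy is the trace over
#' the total count (which for the binary case coincides with
#' `(TP + TN) / (TP + TN + FP + FN)`).
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report`: data frame `per_class` (precision, recall,
#'   f1) plus scalar `accuracy`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    per_class = data.frame(class = rownames(cm), precision = precision,
                           recall = recall, f1 = f1, row.names = NULL),
    accuracy = sum(tp) / total), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  df[-1L] <- lapply(df[-1L], round, digits = 4L)
  print(df, row.names = FALSE)
  cat(sprintf("overall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Best / worst / mean / standard deviation over repeated runs
#'
#' Summarizes the accuracies of repeated independent optimization runs.
#' The standard deviation uses the sample (n - 1) denominator, the usual
#' reporting convention for small run counts; for a single value it is 0.
#'
#' @param accuracies Numeric vector (length >= 1).
#' @return A `run_summary` list: `best`, `worst`, `mean`, `sd`.
#' @export
run_statistics <- function(accuracies) {
  if (length(accuracies) < 1L || !is.numeric(accuracies)) {
    stop("accuracies must contain at least one numeric value")
  }
  structure(list(best = max(accuracies), worst = min(accuracies),
                 mean = mean(accuracies),
                 sd = if (length(accuracies) > 1L) stats::sd(accuracies) else 0),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("best %.4f  worst %.4f  mean %.4f  sd %.4f\n",
              x$best, x$worst, x$mean, x$sd))
  invisible(x)
}

#' Export convergence traces as CSV
#'
#' Writes the best-so-far trace of one or more optimization results in
#' long format (`algorithm, iteration, best_energy[, best_accuracy]`) for
#' plotting. When the objective was `1 - accuracy`, set
#' `as_accuracy = TRUE` to add the non-decreasing accuracy column.
#'
#' @param results A single `optimization_result` or a list of them;
#'   list names override the stored algorithm labels.
#' @param path Output CSV path.
#' @param as_accuracy Add a `best_accuracy = 1 - best_energy` column.
#' @return The exported data frame, invisibly.
#' @export
export_convergence <- function(results, path, as_accuracy = FALSE) {
  if (inherits(results, "optimization_result")) results <- list(results)
  if (length(results) == 0L) stop("results must be non-empty")
  labels <- names(results)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    lab <- if (!is.null(labels) && nzchar(labels[i])) labels[i] else r$algorithm
    data.frame(algorithm = lab, iteration = seq_along(r$trace),
               best_energy = r$trace)
  })
  df <- do.call(rbind, rows)
  if (as_accuracy) df$best_accuracy <- 1 - df$best_energy
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write convergence trace to '%s'", path))
  invisible(df)
}
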