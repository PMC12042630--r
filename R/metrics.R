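#' Per-class classification metrics
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and the
#' standard per-class metrics, all as percentages reported to 2 decimals:
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 = harmonic mean
#' of precision and recall. A class with no predicted positives gets
#' precision 0 (and F1 0 when precision and recall are both 0) rather than
#' NaN. Accuracy is `100 * trace(confusion) / n`.
#'
#' @param truth,predicted equal-length character (or factor) label vectors.
#' @param labels optional character vector fixing class order; defaults to
#'   the sorted union of observed labels.
#' @return an object of class `evaluation_report`: a list with `accuracy`
#'   (percent), `per_class` (data.frame: label, precision, recall, f1,
#'   support), `confusion` (K x K count matrix) and `n_test`.
#' @examples
#' compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
compute_metrics <- function(truth, predicted, labels = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths")
  if (length(truth) == 0L) stop("empty label vectors")
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% labels) || !all(predicted %in% labels))
    stop("labels outside the declared label set")
  tf <- factor(truth, levels = labels)
  pf <- factor(predicted, levels = labels)
  confusion <- table(truth = tf, predicted = pf)
  confusion <- matrix(as.integer(confusion), nrow = length(labels),
                      dimnames = list(truth = labels, predicted = labels))
  n <- length(truth)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    label = labels,
    precision = round(100 * precision, 2),
    recall = round(100 * recall, 2),
    f1 = round(100 * f1, 2),
    support = as.integer(rowSums(confusion)),
    row.names = NULL)
  structure(list(accuracy = round(100 * sum(tp) / n, 2),
                 per_class = per_class,
                 confusion = confusion,
                 n_test = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: accuracy %.2f%% on %d samples\n",
              x$accuracy, x$n_test))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (accuracy, per-class table, counts), `report.csv`
#' (the per-class table) and `confusion.csv` into `dir`.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, n_test = report$n_test,
         per_class = report$per_class,
         confusion = as.data.frame.matrix(report$confusion)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_class, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  invisible(dir)
}
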