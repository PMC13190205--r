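#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total count.  Precision, recall and F1
#' are computed one-vs-rest per class (`TP/(TP+FP)`, `TP/(TP+FN)`,
#' harmonic mean) and macro-averaged; a class with no predicted (or no
#' actual) instances contributes 0 to the affected ratio.
#'
#' @param cm square confusion matrix of non-negative counts, rows = true
#'   classes, columns = predicted classes.
#' @return List with `accuracy`, per-class data frame `by_class`, and
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @examples
#' confusion_metrics(matrix(c(5, 0, 0, 0, 4, 2, 0, 1, 3), 3))$accuracy  # 0.8
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0L || nrow(cm) != ncol(cm) || nrow(cm) < 2L)
    stop("'cm' must be a square confusion matrix with >= 2 classes")
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  by_class <- data.frame(class = colnames(cm) %||% as.character(seq_len(nrow(cm))),
                         precision = precision, recall = recall, f1 = f1,
                         support = rowSums(cm), stringsAsFactors = FALSE)
  list(accuracy = sum(tp) / total,
       by_class = by_class,
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
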