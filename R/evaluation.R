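# Confusion matrices, plain and adjacent-level-tolerant ("revised") metrics,
# and rank correlation.

#' 4x4 confusion matrix of bleeding ranks
#'
#' Rows are actual ranks, columns predicted ranks, both over `0:3`.
#'
#' @param actual,predicted Integer vectors in `[0, 3]`, equal non-zero
#'   length.
#' @return A 4x4 integer matrix with dimnames `0:3`.
#' @export
confusion_matrix4 <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("actual and predicted differ in length")
  if (length(actual) == 0L) stop("empty rank vectors")
  if (any(c(actual, predicted) < 0 | c(actual, predicted) > 3))
    stop("ranks must lie in [0, 3]")
  m <- table(factor(actual, levels = 0:3), factor(predicted, levels = 0:3))
  m <- unclass(m)
  dimnames(m) <- list(actual = 0:3, predicted = 0:3)
  m
}

#' Apply the adjacent-level tolerance to a confusion matrix
#'
#' A prediction one level away from the truth is clinically acceptable (for
#' example, a true score 1 predicted as 0 or 2 counts as correct; predicted
#' as 3 it is still wrong). Every off-diagonal count at distance 1 is moved
#' onto the diagonal of its own row; counts at distance 2 or more stay where
#' they are. The grand total is preserved and the operation is idempotent.
#'
#' @param m A 4x4 confusion matrix.
#' @return The revised 4x4 matrix.
#' @export
revise_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L))) stop("m must be a 4x4 matrix")
  out <- m
  for (t in 1:4) for (p in 1:4) {
    if (abs(t - p) == 1L && out[t, p] > 0) {
      out[t, t] <- out[t, t] + out[t, p]
      out[t, p] <- 0
    }
  }
  out
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' Accuracy is the trace over the total. Precision and recall are derived
#' per class in one-vs-rest fashion (TP on the diagonal, FP the rest of the
#' column, FN the rest of the row) and macro-averaged; classes whose
#' denominator is zero are excluded from the macro mean. With
#' `average = "micro"` the pooled counts are used instead, which in
#' multi-class one-vs-rest makes precision = recall = accuracy.
#'
#' @param m A 4x4 confusion matrix with a positive total.
#' @param average `"macro"` (default) or `"micro"`.
#' @return A list with `accuracy`, `precision`, `recall`.
#' @export
metrics_from_matrix <- function(m, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L))) stop("m must be a 4x4 matrix")
  total <- sum(m)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  acc <- sum(tp) / total
  if (average == "micro") {
    prec <- sum(tp) / sum(tp + fp)
    rec <- sum(tp) / sum(tp + fn)
  } else {
    pd <- tp + fp; rd <- tp + fn
    prec <- mean((tp / pd)[pd > 0])
    rec <- mean((tp / rd)[rd > 0])
  }
  list(accuracy = acc, precision = prec, recall = rec)
}

#' Pearson correlation between two rank vectors
#'
#' Plain Pearson product-moment correlation over the integer rank values,
#' used to measure how closely predicted bleeding levels track the expert
#' consensus. Undefined (an error) when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length, at least 2.
#' @return A number in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2L) stop("need at least two paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Full evaluation report for predicted ranks
#'
#' Bundles the plain and revised confusion matrices, their accuracy /
#' precision / recall, and the Pearson correlation between predictions and
#' truth (NA when either vector is constant).
#'
#' @param actual,predicted Integer rank vectors in `[0, 3]`.
#' @param average Averaging mode for precision/recall; see
#'   [metrics_from_matrix()].
#' @return A list of class `"bleed_eval"`.
#' @export
eval_report <- function(actual, predicted, average = "macro") {
  m <- confusion_matrix4(actual, predicted)
  rm_ <- revise_matrix(m)
  plain <- metrics_from_matrix(m, average)
  rev <- metrics_from_matrix(rm_, average)
  corr <- tryCatch(pearson_correlation(actual, predicted),
                   error = function(e) NA_real_)
  structure(list(matrix = m, revised_matrix = rm_,
                 accuracy = plain$accuracy, precision = plain$precision,
                 recall = plain$recall,
                 revised_accuracy = rev$accuracy,
                 revised_precision = rev$precision,
                 revised_recall = rev$recall,
                 correlation = corr),
            class = "bleed_eval")
}

#' @export
print.bleed_eval <- function(x, ...) {
  cat("Bleeding-rank evaluation\n")
  cat(sprintf("  plain:   accuracy %.3f  precision %.3f  recall %.3f\n",
              x$accuracy, x$precision, x$recall))
  cat(sprintf("  revised: accuracy %.3f  precision %.3f  recall %.3f\n",
              x$revised_accuracy, x$revised_precision, x$revised_recall))
  cat(sprintf("  Pearson correlation: %s\n",
              ifelse(is.na(x$correlation), "undefined", sprintf("%.3f", x$correlation))))
  cat("  confusion matrix (rows = actual, cols = predicted):\n")
  print(x$matrix)
  invisible(x)
}
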