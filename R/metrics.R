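#' Multiclass confusion matrix
#'
#' Counts with rows = actual class and columns = predicted class, in a fixed
#' class order (default [milk_classes()]).
#'
#' @param actual,predicted Vectors of class labels of equal length.
#' @param classes Character vector fixing row/column order; every label must
#'   occur in it.
#' @return Integer matrix of class `"confusion_matrix"` with dimnames
#'   `actual` x `predicted`.
#' @export
confusion_matrix <- function(actual, predicted, classes = milk_classes()) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop_ls("`actual` and `predicted` lengths differ",
            class = "lactospec_argument_error")
  if (length(actual) == 0L)
    stop_ls("no observations to tabulate", class = "lactospec_argument_error")
  unknown <- setdiff(unique(c(actual, predicted)), classes)
  if (length(unknown))
    stop_ls("label not in class order: ", paste(unknown, collapse = ", "),
            class = "lactospec_argument_error")
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

# build a confusion_matrix directly from counts (e.g. a published table)
as_confusion_matrix <- function(counts, classes = milk_classes()) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(classes), ncol(counts) == length(classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Overall accuracy of a confusion matrix
#'
#' Number of proper classifications divided by the total number of
#' observations, i.e. trace over total.
#'
#' @param m A [confusion_matrix()].
#' @return A number in \[0, 1\].
#' @export
overall_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  total <- sum(m)
  if (total == 0) stop_ls("empty confusion matrix",
                          class = "lactospec_argument_error")
  sum(diag(m)) / total
}

#' One-vs-all reduction of a multiclass confusion matrix
#'
#' Collapses the matrix to the binary confusion of `target` versus the rest:
#' TP is the diagonal cell of the target, FN the remainder of its row, FP the
#' remainder of its column, TN everything else. The four cells always sum to
#' the total count.
#'
#' @param m A [confusion_matrix()].
#' @param target Class name present in the matrix.
#' @return A list `TP`, `FN`, `FP`, `TN` of class `"binary_confusion"`.
#' @export
one_vs_all <- function(m, target) {
  stopifnot(inherits(m, "confusion_matrix"))
  classes <- rownames(m)
  if (!target %in% classes)
    stop_ls("`", target, "` is not a class of this matrix",
            class = "lactospec_argument_error")
  t_i <- match(target, classes)
  TP <- m[t_i, t_i]
  FN <- sum(m[t_i, ]) - TP
  FP <- sum(m[, t_i]) - TP
  TN <- sum(m) - TP - FN - FP
  binary_confusion(TP, FN, FP, TN)
}

#' Binary confusion counts
#'
#' @param TP,FN,FP,TN Non-negative integer counts, not all zero.
#' @return A list of class `"binary_confusion"`.
#' @export
binary_confusion <- function(TP, FN, FP, TN) {
  cells <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(cells < 0) || sum(cells) == 0)
    stop_ls("binary confusion cells must be non-negative and not all zero",
            class = "lactospec_argument_error")
  structure(as.list(cells), class = "binary_confusion")
}

#' Class-wise sensitivity, specificity and Matthews correlation coefficient
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A sensitivity or specificity with a zero denominator is returned as `NA`;
#' an MCC with a zero denominator is 0 by convention. MCC is invariant under
#' swapping FP and FN, which is why it survives a transposed binary table.
#'
#' @param b A [binary_confusion()].
#' @return List with `sensitivity`, `specificity` (proportions in \[0, 1\] or
#'   `NA`) and `mcc` (in \[-1, 1\]), class `"classwise_metrics"`.
#' @export
classwise_metrics <- function(b) {
  stopifnot(inherits(b, "binary_confusion"))
  sens <- if (b$TP + b$FN > 0) b$TP / (b$TP + b$FN) else NA_real_
  spec <- if (b$TN + b$FP > 0) b$TN / (b$TN + b$FP) else NA_real_
  structure(list(sensitivity = sens, specificity = spec,
                 mcc = mcc(b$TP, b$FN, b$FP, b$TN)),
            class = "classwise_metrics")
}

#' Matthews correlation coefficient from binary counts
#'
#' @param TP,FN,FP,TN Non-negative counts.
#' @return MCC in \[-1, 1\]; 0 when the denominator is 0.
#' @export
mcc <- function(TP, FN, FP, TN) {
  TP <- as.numeric(TP); FN <- as.numeric(FN)
  FP <- as.numeric(FP); TN <- as.numeric(TN)
  # pair the positive-margin and negative-margin factors so the expression
  # is bitwise symmetric under the FP/FN swap
  den <- sqrt(((TP + FP) * (TP + FN)) * ((TN + FP) * (TN + FN)))
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = actual, columns = predicted), n =",
      sum(x), "\n")
  print(unclass(x))
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * overall_accuracy(x)))
  invisible(x)
}

#' @export
print.binary_confusion <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' @export
print.classwise_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, MCC %.2f\n",
              100 * x$sensitivity, 100 * x$specificity, x$mcc))
  invisible(x)
}
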