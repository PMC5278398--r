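#' Confusion matrix over the six behavior classes
#'
#' Rows are predicted classes and columns actual classes, both in the
#' fixed order NHM, LC, RC, LW, RW, TK; the diagonal holds true positives,
#' off-diagonal row entries are false positives of the row class and
#' off-diagonal column entries its false negatives.
#'
#' @param actual,predicted character vectors of class codes, equal length.
#' @return A 6x6 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("label vectors differ in length")
  a <- behavior_factor(actual)
  p <- behavior_factor(predicted)
  m <- table(predicted = p, actual = a)
  m <- matrix(as.integer(m), nrow = 6, ncol = 6,
              dimnames = list(predicted = behavior_codes(),
                              actual = behavior_codes()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain 6x6 count matrix to a `confusion_matrix`
#'
#' @param m 6x6 nonnegative matrix, rows predicted / columns actual in the
#'   fixed class order.
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 6, ncol(m) == 6, all(m >= 0))
  dimnames(m) <- list(predicted = behavior_codes(), actual = behavior_codes())
  structure(matrix(as.integer(round(m)), 6, 6, dimnames = dimnames(m)),
            class = c("confusion_matrix", "matrix"))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' precision_i = TP_i / (row total), recall_i = TP_i / (column total),
#' F1_i = harmonic mean of the two; the summary F1 is the arithmetic mean
#' of the six per-class F1 scores and accuracy is trace / total. Classes
#' with an empty row or column get `NA` metrics and are reported in the
#' `undefined` field rather than silently set to zero.
#'
#' @param cm a `confusion_matrix`.
#' @return List of class `metrics_report` with `precision`, `recall`,
#'   `f1` (named fractions), `average_f1`, `accuracy`, `n`, `undefined`.
#' @export
behavior_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  tp <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  precision <- ifelse(rs > 0, tp / rs, NA_real_)
  recall <- ifelse(cs > 0, tp / cs, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  names(precision) <- names(recall) <- names(f1) <- behavior_codes()
  undefined <- behavior_codes()[is.na(precision) | is.na(recall)]
  structure(list(precision = precision, recall = recall, f1 = f1,
                 average_f1 = mean(f1),
                 accuracy = sum(tp) / sum(m),
                 n = sum(m),
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- data.frame(precision = round_half_up(100 * x$precision, 1),
                   recall = round_half_up(100 * x$recall, 1),
                   f1 = round_half_up(100 * x$f1, 1))
  print(df)
  cat(sprintf("average F1: %.1f%%   accuracy: %.1f%%   n = %d\n",
              round_half_up(100 * x$average_f1, 1),
              round_half_up(100 * x$accuracy, 1), x$n))
  if (length(x$undefined)) {
    cat("undefined metrics for:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Matches the half-up convention used when percentages are printed to one
#' decimal (base `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Reference confusion matrix
#'
#' The benchmark 6x6 confusion matrix of 20,700 labeled 3-second windows
#' (3,450 per class, 10 subjects) from the original glasses-hinge
#' validation study, shipped as a plain-text fixture. It exercises the
#' metric computations at realistic scale: computing
#' [behavior_metrics()] on it reproduces the study's reported per-class
#' precision, recall and F1 values and the 94.0% average F1.
#'
#' @return A `confusion_matrix`.
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion_matrix.csv",
                      package = "chewsense", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  as_confusion(as.matrix(df))
}

#' Read predictions and compute a metrics report
#'
#' @param path CSV with columns `actual,predicted`.
#' @return A `metrics_report`.
#' @export
evaluate_predictions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  behavior_metrics(confusion(df$actual, df$predicted))
}
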