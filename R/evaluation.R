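#' Confusion matrix from paired label sequences
#'
#' Rows are Predicted, columns are Actual, both in class order base, body,
#' stem, tip (codes 0-3).
#'
#' @param predicted,actual equal-length vectors of 0-based class codes
#' @return a 4x4 integer matrix with dimnames Predicted / Actual
#' @export
confusion_from_pairs <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(predicted) > 0 &&
      (!all(predicted %in% 0:3) || !all(actual %in% 0:3)))
    stop("labels must be class codes 0..3")
  m <- matrix(0L, 4, 4, dimnames = list(Predicted = POD_CLASSES,
                                        Actual = POD_CLASSES))
  for (i in seq_along(predicted))
    m[predicted[i] + 1L, actual[i] + 1L] <- m[predicted[i] + 1L, actual[i] + 1L] + 1L
  m
}

#' Precision / recall report from a confusion matrix
#'
#' Follows the reporting convention of the published benchmark tables this
#' package reproduces: with rows = Predicted and columns = Actual,
#' `precision_c = m[c,c] / colsum_c` and `recall_c = m[c,c] / rowsum_c`
#' (note this maps the textbook definitions onto the printed orientation),
#' both in percent. Totals are unweighted macro averages of the four
#' per-class values. Classes with a zero denominator are reported as `NA`
#' and excluded from the macro average with a warning.
#'
#' @param m a 4x4 confusion matrix (rows Predicted, columns Actual)
#' @return list with `per_class` (data frame: class, precision, recall) and
#'   `total_precision`, `total_recall` (percent)
#' @export
metrics_from_confusion <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)), all(m >= 0))
  precision <- 100 * diag(m) / colSums(m)
  recall <- 100 * diag(m) / rowSums(m)
  precision[colSums(m) == 0] <- NA_real_
  recall[rowSums(m) == 0] <- NA_real_
  if (anyNA(precision) || anyNA(recall))
    warning("empty class row/column; metric undefined for that class and excluded from totals")
  list(per_class = data.frame(class = POD_CLASSES,
                              precision = unname(precision),
                              recall = unname(recall)),
       total_precision = mean(precision, na.rm = TRUE),
       total_recall = mean(recall, na.rm = TRUE))
}

#' Agreement between predicted and manual counts
#'
#' Pearson correlation of the paired counts, its square, the root mean
#' squared error, and the signed per-image errors (actual - predicted) for
#' histogramming.
#'
#' @param predicted,manual paired count vectors, length >= 3
#' @return list with `correlation_coefficient`, `r_squared`, `rmse`, `errors`
#' @export
count_agreement <- function(predicted, manual) {
  if (length(predicted) != length(manual)) stop("counts must be paired")
  if (length(predicted) < 3) stop("need at least 3 paired counts")
  if (sd(predicted) == 0 || sd(manual) == 0)
    stop("zero variance in counts; correlation undefined")
  r <- cor(predicted, manual)
  list(correlation_coefficient = r,
       r_squared = r^2,
       rmse = sqrt(mean((manual - predicted)^2)),
       errors = manual - predicted)
}

#' Histogram of counting errors
#'
#' Bins the signed errors (actual - predicted) into bins of `bin_width`
#' centred on multiples of the width; the bin counts sum to the number of
#' errors.
#'
#' @param errors numeric vector of signed errors
#' @param bin_width bin width
#' @return data frame with `mid` (bin centre) and `count`
#' @export
error_histogram <- function(errors, bin_width = 1) {
  if (length(errors) == 0)
    return(data.frame(mid = numeric(0), count = integer(0)))
  idx <- round(errors / bin_width)
  tab <- table(idx)
  data.frame(mid = as.numeric(names(tab)) * bin_width,
             count = as.integer(tab))
}

#' Reference confusion matrices for the two architectures
#'
#' Published benchmark confusion matrices for LeNet and DenseNet patch
#' classifiers evaluated on real *Arabidopsis* inflorescence test patches,
#' shipped as a regression fixture for the metric definitions in
#' [metrics_from_confusion()].
#'
#' @param arch `"lenet"` or `"densenet"`
#' @return a 4x4 integer matrix (rows Predicted, columns Actual)
#' @export
reference_confusion <- function(arch = c("lenet", "densenet")) {
  arch <- match.arg(arch)
  path <- system.file("extdata", paste0("confusion_", arch, ".tsv"),
                      package = "podquant")
  m <- as.matrix(read.delim(path, row.names = 1))
  dimnames(m) <- list(Predicted = POD_CLASSES, Actual = POD_CLASSES)
  storage.mode(m) <- "integer"
  m
}

#' Scatter plot of predicted versus manual counts
#'
#' @param predicted,manual paired counts
#' @param main plot title
#' @return invisibly, the [count_agreement()] result
#' @export
plot_count_agreement <- function(predicted, manual, main = "Silique counts") {
  ca <- count_agreement(predicted, manual)
  plot(manual, predicted, xlab = "Manual count", ylab = "Predicted count",
       main = sprintf("%s (r = %.3f, RMSE = %.2f)", main,
                      ca$correlation_coefficient, ca$rmse),
       pch = 19, col = "#00000080")
  abline(0, 1, lty = 2)
  invisible(ca)
}

#' Histogram plot of counting errors
#'
#' @param errors signed errors (actual - predicted)
#' @param bin_width bin width
#' @return invisibly, the binned counts
#' @export
plot_error_histogram <- function(errors, bin_width = 1) {
  h <- error_histogram(errors, bin_width)
  graphics::barplot(h$count, names.arg = h$mid,
                    xlab = "Actual - predicted", ylab = "Images")
  invisible(h)
}
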