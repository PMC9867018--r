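#' Harmonic-mean F1 score from precision and recall
#'
#' @param precision,recall values in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)`; 0 when both are 0.
#' @export
#' @examples
#' f1_from_pr(0.864, 0.857)
f1_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Unweighted macro average
#'
#' The committed averaging convention for per-class metrics: the plain
#' arithmetic mean over classes, which is what reconciles per-class tables
#' with overall summary rows. A frequency-weighted mean is available via
#' `weights`.
#'
#' @param values per-class metric values.
#' @param weights optional nonnegative class weights (defaults to equal).
#' @return scalar mean.
#' @export
macro_average <- function(values, weights = NULL) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  if (is.null(weights)) return(mean(values))
  stopifnot(length(weights) == length(values), all(weights >= 0))
  sum(values * weights) / sum(weights)
}

zero_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("zero denominator for %s; reporting 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics report
#'
#' One-vs-rest confusion counts per class with precision, recall,
#' specificity, and F1, their unweighted macro averages, and overall
#' accuracy. Zero-denominator metrics are reported as 0 with a warning.
#'
#' @param true_labels,predicted_labels equal-length integer vectors of class
#'   ids in `0:(num_classes-1)`.
#' @param num_classes number of classes.
#' @return a `metrics_report`: list with `per_class` (tibble), `macro`
#'   (named list), `accuracy`, `n`.
#' @export
#' @examples
#' classification_metrics(c(0, 1, 2, 0), c(0, 1, 1, 0), 3)$accuracy
classification_metrics <- function(true_labels, predicted_labels, num_classes) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (any(!true_labels %in% 0:(num_classes - 1)) ||
      any(!predicted_labels %in% 0:(num_classes - 1))) {
    stop("labels outside 0..(num_classes-1)", call. = FALSE)
  }
  n <- length(true_labels)
  per <- lapply(0:(num_classes - 1), function(c) {
    tp <- sum(true_labels == c & predicted_labels == c)
    fp <- sum(true_labels != c & predicted_labels == c)
    fn <- sum(true_labels == c & predicted_labels != c)
    tn <- n - tp - fp - fn
    precision <- zero_div(tp, tp + fp, sprintf("precision (class %d)", c))
    recall <- zero_div(tp, tp + fn, sprintf("recall (class %d)", c))
    specificity <- zero_div(tn, tn + fp, sprintf("specificity (class %d)", c))
    tibble::tibble(class = c, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall,
                   specificity = specificity,
                   f1 = f1_from_pr(precision, recall))
  })
  per <- dplyr::bind_rows(per)
  structure(
    list(
      per_class = per,
      macro = list(precision = macro_average(per$precision),
                   recall = macro_average(per$recall),
                   specificity = macro_average(per$specificity),
                   f1 = macro_average(per$f1)),
      accuracy = mean(true_labels == predicted_labels),
      n = n
    ),
    class = "metrics_report"
  )
}

#' Segmentation metrics report
#'
#' Pixel confusion over `num_classes` categories (background included as a
#' category), mean intersection-over-union, mean pixel accuracy, and overall
#' pixel accuracy. For class `i`, `IoU_i = P_ii / (sum_j P_ij + sum_j P_ji -
#' P_ii)` and `PA_i = P_ii / sum_j P_ij`; the means run over the classes
#' present in either map (a class absent from both prediction and ground
#' truth is excluded rather than counted as vacuously perfect).
#'
#' @param pred,gt integer class maps (or logical masks, treated as classes
#'   0/1) of equal dimensions.
#' @param num_classes total number of categories including background.
#' @return a `seg_metrics` list: `confusion` (matrix), `per_class` (tibble
#'   with `iou`, `pa`), `miou`, `mpa`, `pixel_accuracy`.
#' @export
#' @examples
#' gt <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
#' pr <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
#' segmentation_metrics(pr, gt)$miou  # 7/12
segmentation_metrics <- function(pred, gt, num_classes = 2) {
  if (is.logical(pred)) pred <- pred * 1L
  if (is.logical(gt)) gt <- gt * 1L
  if (!all(dim(pred) == dim(gt))) {
    stop("prediction and ground-truth dimensions differ", call. = FALSE)
  }
  P <- matrix(0, num_classes, num_classes)
  tab <- table(factor(gt, levels = 0:(num_classes - 1)),
               factor(pred, levels = 0:(num_classes - 1)))
  P[] <- as.numeric(tab)
  present <- which(rowSums(P) + colSums(P) > 0)
  per <- lapply(present, function(i) {
    denom_iou <- sum(P[i, ]) + sum(P[, i]) - P[i, i]
    tibble::tibble(
      class = i - 1L,
      iou = zero_div(P[i, i], denom_iou, sprintf("IoU (class %d)", i - 1)),
      pa = zero_div(P[i, i], sum(P[i, ]), sprintf("PA (class %d)", i - 1))
    )
  })
  per <- dplyr::bind_rows(per)
  structure(
    list(confusion = P, per_class = per,
         miou = mean(per$iou), mpa = mean(per$pa),
         pixel_accuracy = sum(diag(P)) / sum(P)),
    class = "seg_metrics"
  )
}

#' Round metric values for display the way the reports print them
#'
#' Half-up rounding to 3 decimal places; internal values keep full
#' precision.
#' @param x numeric.
#' @return rounded numeric.
#' @export
report_round <- function(x) floor(x * 1000 + 0.5) / 1000

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  cat(sprintf("macro: precision %.3f, recall %.3f, specificity %.3f, F1 %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$specificity, x$macro$f1))
  print(x$per_class)
  invisible(x)
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> MIoU = %.4f, MPA = %.4f, pixel accuracy = %.4f\n",
              x$miou, x$mpa, x$pixel_accuracy))
  invisible(x)
}
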