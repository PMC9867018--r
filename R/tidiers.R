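#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training fit into its loss curve
#' @param x a `pollenseg_fit`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`.
#' @export
tidy.pollenseg_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' One-row summary of a training fit
#' @param x a `pollenseg_fit`.
#' @param ... unused.
#' @return tibble with task, epochs, first/final loss, parameter count.
#' @export
glance.pollenseg_fit <- function(x, ...) {
  tibble::tibble(task = x$task, epochs = length(x$loss),
                 initial_loss = x$loss[1], final_loss = x$loss[length(x$loss)],
                 n_params = n_params(x$model))
}

#' Tidy a collaborative-training state into per-round history
#' @param x a `collab_state`.
#' @param ... unused.
#' @return the history tibble (one row per round, round 0 included).
#' @export
tidy.collab_state <- function(x, ...) x$history

#' One-row summary of a collaborative run
#' @param x a `collab_state`.
#' @param ... unused.
#' @return tibble with rounds run, QC acceptance, initial/final mask IoU
#'   against ground truth (NA without ground truth), final test accuracy.
#' @export
glance.collab_state <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    rounds_run = x$rounds_run,
    qc_accept_rate = mean(x$qc$accepted),
    initial_mask_iou = h$train_mask_iou_vs_gt[1],
    final_mask_iou = h$train_mask_iou_vs_gt[nrow(h)],
    final_test_accuracy = h$cls_test_accuracy[nrow(h)],
    final_test_miou = h$seg_test_miou[nrow(h)]
  )
}

#' Tidy a classification metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return long tibble with `class`, `metric`, `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(
    x$per_class[, c("class", "precision", "recall", "specificity", "f1")],
    -"class", names_to = "metric", values_to = "value"
  )
}

#' One-row summary of a classification metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble with accuracy and macro-averaged metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 precision = x$macro$precision, recall = x$macro$recall,
                 specificity = x$macro$specificity, f1 = x$macro$f1)
}

#' Tidy a segmentation metrics report
#' @param x a `seg_metrics`.
#' @param ... unused.
#' @return per-class tibble with `iou` and `pa`.
#' @export
tidy.seg_metrics <- function(x, ...) x$per_class

#' One-row summary of a segmentation metrics report
#' @param x a `seg_metrics`.
#' @param ... unused.
#' @return tibble with `miou`, `mpa`, `pixel_accuracy`.
#' @export
glance.seg_metrics <- function(x, ...) {
  tibble::tibble(miou = x$miou, mpa = x$mpa, pixel_accuracy = x$pixel_accuracy)
}
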