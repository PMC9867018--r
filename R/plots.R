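# ggplot2 views of the result types

raster_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot a grayscale micrograph, optionally with a mask outline
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param mask optional logical mask drawn as a translucent overlay.
#' @return a ggplot object.
#' @export
plot_micrograph <- function(image, mask = NULL) {
  df <- raster_df(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    md <- raster_df(mask, "fg")
    md <- md[md$fg, , drop = FALSE]
    p <- p + ggplot2::geom_tile(data = md, fill = "red", alpha = 0.25)
  }
  p
}

#' Plot a Grad-CAM heat map
#' @param object a `cam_heatmap`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cam_heatmap <- function(object, ...) {
  df <- raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activation",
                  title = sprintf("Grad-CAM, class %d", object$target_class)) +
    ggplot2::theme_minimal()
}

#' Plot the loss curve of a training fit
#' @param object a `pollenseg_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pollenseg_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("%s training loss", object$task)) +
    ggplot2::theme_minimal()
}

#' Plot per-round history of a collaborative run
#' @param object a `collab_state`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.collab_state <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("round", "cls_test_accuracy", "seg_test_miou",
                       "train_mask_iou_vs_gt")],
    -"round", names_to = "metric", values_to = "value"
  )
  h <- h[!is.na(h$value), , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$round, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = "Collaborative learning rounds", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
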