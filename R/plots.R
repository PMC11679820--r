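#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a confusion matrix
#'
#' @param object A `fall_confusion` matrix.
#' @param ... Unused.
#' @return A ggplot object: true classes as rows, predicted as columns,
#'   with counts printed in each cell.
#' @method autoplot fall_confusion
#' @export
autoplot.fall_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object of the fall-vs-rest ROC curve with its AUC.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(colour = "#d95f02") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("Fall vs. rest ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Training curves of a fitted classifier
#'
#' @param object A trained `fall_classifier`.
#' @param ... Unused.
#' @return A ggplot object of train/validation loss and accuracy by epoch.
#' @method autoplot fall_classifier
#' @export
autoplot.fall_classifier <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(
    h, c("train_loss", "val_loss", "train_acc", "val_acc"),
    names_to = c("split", "metric"), names_sep = "_"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Central-point trajectories of a few clips
#'
#' Plots the image-y coordinate of the central body point over time for
#' a sample of clips per class; descents (falls, lying down) move
#' downward in the image, i.e. y increases.
#'
#' @param df Keypoint tibble.
#' @param clips_per_class Clips sampled per class.
#' @return A ggplot object.
#' @export
plot_central_trajectories <- function(df, clips_per_class = 2L) {
  cp <- central_point(df)
  cp$label <- df$label
  keep <- cp |>
    dplyr::distinct(.data$label, .data$clip_id) |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = clips_per_class) |>
    dplyr::ungroup()
  cp <- dplyr::semi_join(cp, keep, by = c("label", "clip_id"))
  ggplot2::ggplot(cp, ggplot2::aes(.data$frame, .data$cy, group = .data$clip_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frame", y = "central-point image y (reversed)") +
    ggplot2::theme_minimal()
}
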