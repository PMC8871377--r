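#' @import ggplot2
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic or loaded B-scan
#'
#' @param object an `oct_image`.
#' @param ... unused.
#' @return a ggplot raster of the scan, origin at the top-left as OCT
#'   viewers draw it.
#' @method autoplot oct_image
#' @export
autoplot.oct_image <- function(object, ...) {
  px <- as_gray(object$pixels)
  df <- tibble(row = rep(seq_len(nrow(px)), times = ncol(px)),
               col = rep(seq_len(ncol(px)), each = nrow(px)),
               intensity = as.vector(px))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = object$label, x = NULL, y = NULL, fill = "I") +
    theme_minimal()
}

#' @export
plot.oct_image <- function(x, ...) print(autoplot.oct_image(x, ...))

#' ROC curve plot for a metrics report
#'
#' @param object a `metrics_report` with a ROC component.
#' @param ... unused.
#' @return a ggplot of the ROC curve with the AUC in the subtitle.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  if (is.null(object$roc)) abort("report has no ROC curve (single class or no scores)")
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_fixed() +
    labs(title = "ROC curve",
         subtitle = sprintf("AUC = %.4f", round_half_up(object$auc, 4)),
         x = "False positive rate", y = "True positive rate") +
    theme_minimal()
}

#' Training-history plot for an embedding model
#'
#' @param object an `embedding_model` with at least one trained epoch.
#' @param ... unused.
#' @return a ggplot of per-epoch loss and accuracy, faceted by metric.
#' @method autoplot embedding_model
#' @export
autoplot.embedding_model <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) abort("model has no training history")
  long <- tibble(
    epoch = rep(h$epoch, 4),
    metric = rep(c("loss", "loss", "accuracy", "accuracy"), each = nrow(h)),
    split = rep(c("train", "validation", "train", "validation"),
                each = nrow(h)),
    value = c(h$train_loss, h$val_loss, h$train_acc, h$val_acc))
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$split)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' LOF score distribution plot
#'
#' @param predictions a prediction tibble from [predict.oct_pipeline()].
#' @param threshold optional decision threshold to draw.
#' @return a ggplot histogram of LOF scores, filled by true label when
#'   available.
#' @export
plot_lof_scores <- function(predictions, threshold = NULL) {
  fill <- if ("binary_label" %in% names(predictions)) "binary_label" else NULL
  p <- ggplot(predictions, aes(x = .data$lof_score)) +
    (if (is.null(fill)) geom_histogram(bins = 40)
     else geom_histogram(aes(fill = .data$binary_label), bins = 40,
                         position = "identity", alpha = 0.6)) +
    scale_x_log10() +
    labs(x = "LOF score (log scale)", y = "Images", fill = NULL) +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
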