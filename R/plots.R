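# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#' @param object a `pr_curve` tibble from [pr_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       colour = factor(.data$class_id))) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Class",
                  title = "Precision-recall curve") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report (PR curves, AP annotations)
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  pr <- object$pr
  labs <- object$per_class
  pr$class <- labs$class[match(pr$class_id, labs$class_id)]
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Class",
                  subtitle = sprintf("mAP50 = %.3f", object$map50)) +
    ggplot2::theme_minimal()
}

#' Plot the loss history of a training run
#' @param object a `seedling_fit`.
#' @param ... unused.
#' @return a ggplot with per-component loss curves.
#' @export
autoplot.seedling_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("box", "cls", "dfl", "total"),
                           names_to = "component", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL,
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Heatmap of a detection confusion matrix
#' @param cm matrix from [confusion_matrix()].
#' @param normalize show row-normalized proportions.
#' @return a ggplot.
#' @export
plot_confusion <- function(cm, normalize = TRUE) {
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1L, pmax(rs, 1), "/")
  }
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "pred", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted", y = "True", fill = NULL,
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
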