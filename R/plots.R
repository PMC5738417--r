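# ggplot2 displays for the pipeline's result objects.

#' @export
autoplot.nm_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("reference", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$reference,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  100 * accuracy(object))) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param history Tibble from a trained `nm_net` (`tidy()` output).
#' @return A ggplot.
#' @export
plot_history <- function(history) {
  long <- tidyr::pivot_longer(history, -"step",
                              names_to = c("set", "metric"),
                              names_sep = "_", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "mini-batch update", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a field with optional nucleus outlines
#'
#' @param field An `nm_field`.
#' @param labels Optional integer label map to outline.
#' @return A ggplot.
#' @export
plot_field <- function(field, labels = NULL) {
  px <- field$pixels
  df <- expand.grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- as.vector(px)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "counts")
  if (!is.null(labels)) {
    edge <- labels > 0 &
      (shift_mat(labels, 1, 0) != labels | shift_mat(labels, 0, 1) != labels |
         shift_mat(labels, -1, 0) != labels | shift_mat(labels, 0, -1) != labels)
    de <- which(edge, arr.ind = TRUE)
    p <- p + ggplot2::annotate("point", x = de[, 2], y = de[, 1],
                               colour = "red", size = 0.1)
  }
  p
}

#' Scatter plot of a 2-D embedding
#'
#' @param embedding Tibble from [tsne_embed()].
#' @param labels Optional point labels (colour).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) df$label <- as.character(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7) + ggplot2::theme_minimal()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7) +
      ggplot2::labs(colour = NULL) + ggplot2::theme_minimal()
  }
}
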