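#' Plot a tile density map
#'
#' @param object A [density_map()] matrix.
#' @param ... Unused.
#' @return A ggplot heatmap of per-tile counts (rows increase downward, as on
#'   the slide).
#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  df <- tibble::as_tibble(expand.grid(
    row = seq_len(nrow(object)) - 1L, col = seq_len(ncol(object)) - 1L
  ))
  df$count <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "tile column", y = "tile row",
      fill = paste0(attr(object, "cell_class") %||% "cell", "s / tile")
    )
}

#' Plot a synthetic scene
#'
#' @param object A `wsi_scene`.
#' @param ... Unused.
#' @return A ggplot of cell centres coloured by class.
#' @method autoplot wsi_scene
#' @export
autoplot.wsi_scene <- function(object, ...) {
  ggplot2::ggplot(
    object$cells,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cell_class)
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, object$width), ylim = c(object$height, 0)) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL)
}

#' Observed versus predicted recurrence score
#'
#' @param model An `rs_model`.
#' @param data Data with the model features and the response.
#' @param response Response column (default `"rs"`).
#' @return A ggplot scatter with the identity line.
#' @export
plot_rs_fit <- function(model, data, response = "rs") {
  df <- tibble::tibble(
    observed = as.numeric(data[[response]]),
    predicted = predict_rs(model, data)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed RS", y = "predicted RS")
}

#' Heatmap of a risk-category confusion matrix
#'
#' @param m A 3x3 matrix from [confusion3()].
#' @return A ggplot tile plot with counts printed in the cells.
#' @export
plot_confusion3 <- function(m) {
  df <- tibble::as_tibble(expand.grid(
    gt = rownames(m), pred = colnames(m), stringsAsFactors = FALSE
  ))
  df$count <- as.vector(m)
  lev <- risk_levels()
  df$gt <- factor(df$gt, levels = rev(lev))
  df$pred <- factor(df$pred, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$gt, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "ground truth", fill = "n")
}
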