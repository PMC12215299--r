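#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_raster_df <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  tibble::tibble(
    row = rep(seq_len(H), W),
    col = rep(seq_len(W), each = H),
    fill = grDevices::rgb(px[, , 1], px[, , 2], px[, , 3], maxColorValue = 255)
  )
}

#' Plot a pressure image
#'
#' @param object A [pressure_image()].
#' @param ... Unused.
#' @return A ggplot (row 1 drawn at the top).
#' @method autoplot pressure_image
#' @export
autoplot.pressure_image <- function(object, ...) {
  df <- image_raster_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a binary pressure mask
#'
#' @param object A `pressure_mask`.
#' @param ... Unused.
#' @return A ggplot; marked pixels dark on white.
#' @method autoplot pressure_mask
#' @export
autoplot.pressure_mask <- function(object, ...) {
  m <- unclass(object)
  H <- nrow(m); W <- ncol(m)
  df <- tibble::tibble(
    row = rep(seq_len(H), W),
    col = rep(seq_len(W), each = H),
    marked = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$marked)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "grey20"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot an elbow curve
#'
#' Inertia against the number of clusters; look for the k past which the drop
#' flattens.
#'
#' @param object A `pedo_elbow` tibble from [elbow_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pedo_elbow
#' @export
autoplot.pedo_elbow <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares (inertia)") +
    ggplot2::theme_minimal()
}

#' Plot silhouette widths by cluster
#'
#' @param object The result of [silhouette_score()].
#' @param ... Unused.
#' @return A ggplot of sorted per-point silhouette widths, faceted by cluster.
#' @export
plot_silhouette <- function(object, ...) {
  w <- dplyr::arrange(object$widths, .data$cluster, dplyr::desc(.data$width))
  w$rank <- seq_len(nrow(w))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$rank, y = .data$width,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = NULL, y = "silhouette width", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram
#'
#' @param x A `pedo_dendrogram`.
#' @param ... Passed to [plot()] on the underlying `hclust` object.
#' @return `x`, invisibly.
#' @export
plot.pedo_dendrogram <- function(x, ...) {
  plot(x$hclust, main = sprintf("%s linkage (%s)", x$linkage, x$metric),
       xlab = "", sub = "", ...)
  invisible(x)
}
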