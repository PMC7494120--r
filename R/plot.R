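#' Plot a shape graph
#'
#' Draws boundaries (black), in-graph edges (blue), out-graph edges (orange),
#' and frame edges (grey); parabolic edges are drawn as chords (adequate at
#' pixel scale for display).
#'
#' @param object a `shape_graph` (annotated graphs are coloured by side).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.shape_graph <- function(object, ...) {
  e <- object$edges[!is.na(object$edges$v2), ]
  seg <- tibble(
    x = object$vertices$x[e$v1], y = object$vertices$y[e$v1],
    xend = object$vertices$x[e$v2], yend = object$vertices$y[e$v2],
    side = if (!is.null(e$side)) e$side else "graph")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$side),
      linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      "in" = "#2166ac", out = "#e08214", frame = "grey70",
      graph = "#2166ac")) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "side")
  if (!is.null(object$boundaries)) {
    bnd <- list_rbind(pmap(
      list(object$boundaries$boundary_id, object$boundaries$points),
      function(id, pts) {
        ring <- rbind(pts, pts[1, , drop = FALSE])
        tibble(boundary_id = id, x = ring[, 1], y = ring[, 2])
      }))
    p <- p + ggplot2::geom_path(
      data = bnd,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$boundary_id),
      colour = "black", linewidth = 0.4)
  }
  p
}

#' @export
plot.shape_graph <- function(x, ...) print(autoplot.shape_graph(x, ...))

#' Plot a width or boundary profile
#'
#' @param profile tibble from [width_profile()] (`arc`, `radius`) or
#'   [boundary_profile()] (`arc`, `height`).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ycol <- if ("radius" %in% colnames(profile)) "radius" else "height"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$arc, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "arc length (px)", y = paste(ycol, "(px)"))
}

#' Plot per-image boundary-type histograms
#'
#' @param histograms tibble from [image_histograms()].
#' @param images optional subset of image ids.
#' @return A ggplot object (one facet per image).
#' @export
plot_histograms <- function(histograms, images = NULL) {
  h <- histograms
  if (!is.null(images)) h <- h[h$image_id %in% images, ]
  long <- tidyr::pivot_longer(h, dplyr::starts_with("type_"),
                              names_to = "type", values_to = "count")
  long$type <- as.integer(sub("type_", "", long$type))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$count)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~image_id) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "boundary type", y = "count")
}

#' Plot the PCA embedding of an image set
#'
#' @param embedding result of [pca_embed()].
#' @param labels optional class label per image.
#' @return A ggplot object.
#' @export
plot_pca <- function(embedding, labels = NULL) {
  sc <- embedding$scores
  sc$label <- if (is.null(labels)) "image" else as.character(labels)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * embedding$explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * embedding$explained[2]))
}
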