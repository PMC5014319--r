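#' Plot a pictogram
#'
#' Renders the binary pictogram as a raster with the image convention
#' (origin top-left).
#'
#' @param object A `"pictogram"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pictogram <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(object)), each = nrow(object)),
    y = rep(seq_len(nrow(object)), times = ncol(object)),
    on = as.vector(unclass(object)) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black"),
                               guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot the measurement distribution of an index state
#'
#' Bar chart of the Born probabilities `|amplitude|^2` over the tuple
#' indices; after Grover amplification the marked tuples stand out.
#'
#' @param object An `"index_state"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.index_state <- function(object, ...) {
  df <- tibble::tibble(
    index = seq_along(object$amplitudes),
    probability = object$amplitudes^2
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$probability)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "tuple index", y = "measurement probability") +
    ggplot2::theme_minimal()
}

#' Plot a scene with its object boxes
#'
#' The pictogram (if the scene was built from one this is the noisy render;
#' otherwise the clean render of its object table) overlaid with each
#' object's bounding box and address.
#'
#' @param scene A `"scene"`.
#' @param pictogram Optional pictogram to draw beneath the boxes; defaults
#'   to a clean render of the scene's objects.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, pictogram = NULL) {
  if (is.null(pictogram)) pictogram <- render_pictogram(scene$objects, scene$canvas)
  boxes <- scene$objects
  autoplot.pictogram(pictogram) +
    ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE, colour = "red", fill = NA,
      ggplot2::aes(xmin = .data$x0 + 0.5, xmax = .data$x0 + .data$width + 0.5,
                   ymin = .data$y0 + 0.5, ymax = .data$y0 + .data$height + 0.5)
    ) +
    ggplot2::geom_text(
      data = boxes, inherit.aes = FALSE, colour = "red", size = 3,
      ggplot2::aes(x = .data$x0 + .data$width / 2,
                   y = .data$y0 - 1.5, label = .data$address)
    )
}
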