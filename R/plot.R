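#' Plot an embedding as a scatter map
#'
#' Points are placed at their grid coordinates; overlapping compounds (same
#' nearest reference scaffold) are counted into the point size. Row 0 is at
#' the bottom (y increases upwards), matching the coordinate semantics.
#'
#' @param object A `hilbert_embedding`.
#' @param colour_by Optional column name used for the point color.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot hilbert_embedding
#' @export
autoplot.hilbert_embedding <- function(object, colour_by = NULL, ...) {
  n_side <- attr(object, "n_side")
  df <- as_tibble(object)
  p <- if (is.null(colour_by)) {
    counts <- dplyr::count(df, .data$x, .data$y)
    ggplot2::ggplot(counts, ggplot2::aes(x = .data$x, y = .data$y,
                                         size = .data$n)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::scale_size_area(max_size = 4)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data[[colour_by]])) +
      ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::coord_fixed(xlim = c(-0.5, n_side - 0.5),
                         ylim = c(-0.5, n_side - 0.5)) +
    ggplot2::labs(x = "x", y = "y",
                  title = sprintf("Hilbert embedding (z = %d)",
                                  attr(object, "z"))) +
    ggplot2::theme_minimal()
}

#' Plot a coverage matrix as a heatmap
#'
#' @param m A matrix from [coverage_matrix()] (row `y + 1`, column `x + 1`).
#' @return A ggplot object with cell intensity proportional to the count.
#' @export
plot_coverage <- function(m) {
  df <- tibble(
    x = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    count = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot the reference scaffolds folded onto the curve
#'
#' @param space A `scaffold_space`.
#' @param z Curve order.
#' @return A ggplot object tracing the scaffold ranks along the folded curve.
#' @export
plot_space_curve <- function(space, z) {
  co <- space_coordinates(space, z)
  ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$rank)) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("Reference scaffolds on the order-%d curve",
                                  z))
}
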