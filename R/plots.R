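# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

rects_df <- function(nest) {
  r <- all_rects(nest)
  tibble(x0 = r[, "x0"], y0 = r[, "y0"], x1 = r[, "x1"], y1 = r[, "y1"],
         kind = rep(c("chamber", "corridor"),
                    c(nrow(nest$chambers), nrow(nest$corridors))))
}

#' Plot the nest layout
#'
#' @param nest A [nest_geometry()].
#' @return A ggplot object.
#' @export
plot_nest <- function(nest) {
  df <- rects_df(nest)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1,
                                    fill = .data$kind),
                       colour = "grey30", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(chamber = "grey95",
                                          corridor = "grey80"),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
  if (!is.null(nest$entrance_point)) {
    p <- p + ggplot2::annotate("point", x = nest$entrance_point[1],
                               y = nest$entrance_point[2], shape = 17)
  }
  p
}

#' Plot tracks over the nest
#'
#' @param tracks Complete track tibble.
#' @param nest A [nest_geometry()].
#' @param alpha Path transparency.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, nest, alpha = 0.2) {
  plot_nest(nest) +
    ggplot2::geom_path(
      data = filter(tracks, .data$presence != "outside"),
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$ant_id,
                   colour = .data$ant_id),
      alpha = alpha, show.legend = FALSE)
}

#' Plot a spatial partition
#'
#' Mean entrance distance per ant, coloured by spatial group (group 0 =
#' outside-only ants).
#'
#' @param object A `spatial_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spatial_partition <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(group = factor(.data$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_dist,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, show.legend = FALSE) +
    ggplot2::labs(x = "spatial group", y = "mean entrance distance (mm)")
}

#' Plot fitted movement surfaces
#'
#' @param object An [fit_sde()] result.
#' @param surface `"motility"` or `"potential"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sde_fit <- function(object, surface = c("motility", "potential"),
                             ...) {
  surface <- match.arg(surface)
  df <- object$surfaces
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_x, y = .data$cell_y,
                                   fill = .data[[surface]])) +
    ggplot2::geom_tile(width = object$grid_mm, height = object$grid_mm) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = surface)
}

#' Plot the decorrelated local-density series
#'
#' @param decorrelated Result of [decorrelate()].
#' @return A ggplot object showing the per-second mean density and the
#'   retained subsample points.
#' @export
plot_density_series <- function(decorrelated) {
  ggplot2::ggplot(decorrelated$mean_series,
                  ggplot2::aes(x = .data$t, y = .data$mean_density)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(data = decorrelated$subsampled, colour = "black") +
    ggplot2::labs(x = "time (s)", y = "mean local density (ants)")
}
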