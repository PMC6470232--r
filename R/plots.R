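#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an activation map
#'
#' Raster of the inverse-distance-interpolated mean concentration change
#' with channel midpoints overlaid.
#'
#' @param object An [activation_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = object$channel_means, shape = 21,
                        fill = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * c ~ (mu * M))) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(toupper(object$chromophore), ", ",
                                 object$condition),
                  x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a directed region network as a matrix
#'
#' Tile plot of the 30 directed inter-regional coupling strengths, one
#' facet per band (and condition, if several are present).
#'
#' @param networks Output of [aggregate_regions()].
#' @return A ggplot.
#' @export
plot_region_network <- function(networks) {
  networks <- tibble::as_tibble(networks)
  labs <- region_labels()
  networks$source <- factor(networks$source, labs)
  networks$target <- factor(networks$target, labs)
  ggplot2::ggplot(networks,
                  ggplot2::aes(x = .data$target, y = .data$source,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(condition ~ band) +
    ggplot2::scale_fill_viridis_c(name = expression(sigma ~ (rad / s))) +
    ggplot2::labs(x = "target region", y = "source region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a few channels of a recording
#'
#' @param object A [hemo_recording()].
#' @param channels Channels to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hemo_recording
#' @export
autoplot.hemo_recording <- function(object,
                                    channels = utils::head(object$channels, 4),
                                    ...) {
  df <- as_tibble(object) |>
    dplyr::filter(.data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$chromophore)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(hbo = "#c0392b",
                                            hhb = "#2980b9")) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * c ~ (mu * M))) +
    ggplot2::theme_minimal()
}
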