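#' Hex-binned density map of hand-centre locations
#'
#' Renders the classical hex map of where hand centres sit in the visual
#' scene, optionally facetted by hand side, with the frame midlines overlaid.
#' Hexagonal binning is a rendering choice; for the exact-count computational
#' grid see [density_grid()].
#'
#' @param records Hand-record tibble from [explode_hands()].
#' @param bins Number of hexagon bins across the x axis.
#' @param by_side Facet the map by hand side.
#' @return A ggplot object.
#' @export
plot_hand_density <- function(records, bins = 40, by_side = FALSE) {
  if (nrow(records) == 0) abort("no records to plot")
  w <- records$frame_width[1]
  h <- records$frame_height[1]
  geom <- if (requireNamespace("hexbin", quietly = TRUE)) {
    ggplot2::geom_hex(bins = bins)
  } else {
    ggplot2::geom_bin2d(bins = bins)
  }
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$x, y = .data$y)) +
    geom +
    ggplot2::geom_hline(yintercept = h / 2, linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = w / 2, linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "frames") +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(0, h), expand = FALSE) +
    ggplot2::labs(x = "x (pixels)", y = "y (pixels, Cartesian)") +
    ggplot2::theme_minimal()
  if (by_side) p <- p + ggplot2::facet_wrap(~side)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.density_grid <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                 fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = object$frame_height / 2,
                        linetype = "dashed", colour = "white",
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$frame_width / 2,
                        linetype = "dashed", colour = "white",
                        linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "frames") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (pixels)", y = "y (pixels, Cartesian)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.occupancy_table <- function(object, ...) {
  object$pooled |>
    ggplot2::ggplot(ggplot2::aes(x = .data$zone, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste0(object$partition, " zone"), y = "frames (%)",
      title = sprintf("Occupancy (hand: %s, contact: %s)",
                      object$hand, object$contact)
    ) +
    ggplot2::theme_minimal()
}
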