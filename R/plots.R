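# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an en-face thickness map
#'
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @return A ggplot raster of thickness in um with the ONH marked.
#' @method autoplot thickness_map
#' @export
autoplot.thickness_map <- function(object, ...) {
  nx <- nrow(object$values); ny <- ncol(object$values)
  co <- enface_coords(nx, ny, object$dx_um, object$dy_um)
  df <- tidyr::expand_grid(y_um = co$y, x_um = co$x)
  df$thickness_um <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$onh_center_um[1],
                      y = object$onh_center_um[2], shape = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$layer, "thickness"),
                  fill = "µm", x = "x (µm)", y = "y (µm)")
}

#' Plot a vessel mask
#'
#' @param object A `vessel_mask`.
#' @param ... Unused.
#' @return A ggplot raster: vessel pixels, with excluded regions greyed.
#' @method autoplot vessel_mask
#' @export
autoplot.vessel_mask <- function(object, ...) {
  nx <- nrow(object$mask); ny <- ncol(object$mask)
  co <- enface_coords(nx, ny, object$dx_um, object$dy_um)
  df <- tidyr::expand_grid(y_um = co$y, x_um = co$x)
  df$state <- dplyr::case_when(
    as.vector(object$excluded) ~ "excluded",
    as.vector(object$mask) ~ "vessel",
    TRUE ~ "background"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "black",
                                          vessel = "white",
                                          excluded = "grey40")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$plexus, "vessel mask"),
                  x = "x (µm)", y = "y (µm)")
}

#' Plot a swim trajectory inside the pool
#'
#' @param traj Trajectory tibble (`t_s`, `x_m`, `y_m`).
#' @param geom A [pool_geometry()].
#' @return A ggplot of the path, pool wall and platform.
#' @export
plot_trajectory <- function(traj, geom) {
  th <- seq(0, 2 * pi, length.out = 181)
  pool <- tibble(x = geom$pool_radius * cos(th), y = geom$pool_radius * sin(th))
  plat <- tibble(x = geom$platform_center[1] + geom$platform_radius * cos(th),
                 y = geom$platform_center[2] + geom$platform_radius * sin(th))
  ggplot2::ggplot(traj, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$t_s)) +
    ggplot2::geom_path(data = pool, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_path(data = plat, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "t (s)")
}

#' Spaghetti plot of a longitudinal cohort parameter
#'
#' @param cohort Cohort tibble (long format with `value`).
#' @param layer Layer to plot.
#' @return A ggplot of per-animal eye-averaged trajectories by group.
#' @export
plot_cohort <- function(cohort, layer = "TOTAL") {
  d <- cohort |>
    dplyr::filter(.data$layer == !!layer) |>
    dplyr::group_by(.data$animal, .data$genotype, .data$sex, .data$week) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$week, .data$value,
                                  group = .data$animal,
                                  colour = interaction(.data$genotype, .data$sex))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "age (weeks)", y = paste(layer, "thickness (µm)"),
                  colour = "group")
}
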