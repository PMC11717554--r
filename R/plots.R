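#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster layer
#'
#' @param object A `spread_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spread_raster
#' @export
autoplot.spread_raster <- function(object, ...) {
  df <- as_tibble.spread_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot a synthetic landscape: DEM, water, trails and station
#'
#' @param object A `landscape_bundle`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot landscape_bundle
#' @export
autoplot.landscape_bundle <- function(object, ...) {
  df <- as_tibble.spread_raster(object$dem)
  df$value[as.vector(object$water_mask$values)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = object$trails,
                       ggplot2::aes(group = .data$trail),
                       colour = "brown", linewidth = 0.6) +
    ggplot2::annotate("point", x = object$station[1], y = object$station[2],
                      shape = 17, size = 3, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "steelblue",
                                  name = "elevation (m)") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot a density surface
#'
#' @param object A `density_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_surface
#' @export
autoplot.density_surface <- function(object, ...) {
  autoplot.spread_raster(object$raster) +
    ggplot2::labs(fill = "normalised KDE")
}

#' Plot the replicate-averaged arrival-year map
#'
#' @param object An `occupancy_history`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occupancy_history
#' @export
autoplot.occupancy_history <- function(object, ...) {
  autoplot.spread_raster(object$mean_arrival) +
    ggplot2::labs(fill = "mean arrival year",
                  title = sprintf("%s, %d replicate(s)", object$scenario,
                                  object$n_replicates))
}

#' Plot the null distribution of a randomisation test
#'
#' Histogram of the null median luminances with the observed median marked.
#'
#' @param object A `randomisation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot randomisation_result
#' @export
autoplot.randomisation_result <- function(object, ...) {
  df <- tibble::tibble(median_luminance = object$null_medians)
  ggplot2::ggplot(df, ggplot2::aes(.data$median_luminance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_median,
                        colour = "darkgreen", linewidth = 1) +
    ggplot2::labs(x = "median luminance under joint shifts", y = "count",
                  subtitle = sprintf("p = %.3g (n = %d)", object$p_value,
                                     object$n))
}

#' Plot a distance profile
#'
#' @param profile A tibble from [distance_profile()].
#' @return A ggplot.
#' @export
plot_distance_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$bin_mid, .data$mass)) +
    ggplot2::geom_col(width = diff(profile$bin_hi[1:2] - profile$bin_lo[1:2]),
                      fill = "grey60") +
    ggplot2::labs(x = "distance from station (m)", y = "probability mass")
}

#' Plot fitted kernels over the distance histogram
#'
#' @param ranking A `kernel_ranking`.
#' @param sample The `distance_sample` the ranking was fitted to.
#' @param top Number of top-ranked families to draw.
#' @return A ggplot.
#' @export
plot_kernel_fits <- function(ranking, sample, top = 3) {
  d <- sample$distances
  grid <- seq(0, max(d), length.out = 300)
  curves <- dplyr::bind_rows(lapply(utils::head(ranking, top), function(f) {
    fam <- kernel_family(f$family)
    tibble::tibble(family = f$family, distance = grid,
                   density = fam$pdf(grid, f$params))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(distance = d),
      ggplot2::aes(.data$distance, ggplot2::after_stat(density)),
      bins = ceiling(log2(length(d))) + 1, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$distance, .data$density,
                                    colour = .data$family),
                       linewidth = 0.8) +
    ggplot2::labs(x = "establishment distance (m)", y = "density")
}
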