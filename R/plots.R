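state_palette <- c(resident = "black", outward = "#7b3294",
                   inward = "#008837", migratory = "#7b3294")

#' Plot east-west movement coloured by behavioural state
#'
#' Longitude against date for each fish, coloured by the decoded state:
#' black for residence, purple for outward migration, green for inward.
#'
#' @param tracks Track tibble.
#' @param decoded Decoded step tibble from [decode_states()].
#' @return A ggplot object.
#' @export
plot_track_states <- function(tracks, decoded) {
  df <- tracks |>
    dplyr::inner_join(dplyr::select(decoded, "fish_id", "date", "state"),
                      by = c("fish_id", "date"))
  ggplot2::ggplot(df, ggplot2::aes(.data$date, .data$lon,
                                   colour = .data$state,
                                   group = .data$fish_id)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = state_palette) +
    ggplot2::labs(x = NULL, y = "Longitude (°E)", colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot fitted emission distributions
#'
#' Normal state-conditional densities of the daily step observation under a
#' fitted behaviour-switching model.
#'
#' @param object An `sbt_hmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.sbt_hmm <- function(object, ...) {
  p <- object$params
  grid <- tidyr::expand_grid(
    state = factor(p$state_labels, levels = p$state_labels),
    d_t = seq(min(p$means - 4 * p$sds), max(p$means + 4 * p$sds),
              length.out = 400))
  grid$density <- dnorm(grid$d_t, p$means[as.character(grid$state)],
                        p$sds[as.character(grid$state)])
  ggplot2::ggplot(grid, ggplot2::aes(.data$d_t, .data$density,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = state_palette) +
    ggplot2::labs(x = "Daily change in distance to GAB (km)", y = "Density",
                  colour = "State") +
    ggplot2::theme_minimal()
}

#' Plot departure and return phenology
#'
#' Circular densities of departure and return day-of-year, drawn on a linear
#' day axis with the peak days marked.
#'
#' @param departures,returns `circular_density` objects.
#' @return A ggplot object.
#' @export
plot_phenology <- function(departures, returns) {
  df <- dplyr::bind_rows(
    tibble::tibble(doy = departures$grid_doy, density = departures$density,
                   event = "departure"),
    tibble::tibble(doy = returns$grid_doy, density = returns$density,
                   event = "return"))
  peaks <- tibble::tibble(
    event = c("departure", "return"),
    doy = c(circular_peak(departures), circular_peak(returns)))
  ggplot2::ggplot(df, ggplot2::aes(.data$doy, .data$density,
                                   colour = .data$event)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = peaks,
                        ggplot2::aes(xintercept = .data$doy,
                                     colour = .data$event),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(departure = "#2c7fb8",
                                            return = "#d95f02")) +
    ggplot2::labs(x = "Day of year", y = "Density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot state proportions by day of year
#'
#' @param props Tibble from [state_proportion_by_doy()].
#' @return A ggplot object.
#' @export
plot_state_doy <- function(props) {
  ggplot2::ggplot(props, ggplot2::aes(.data$doy, .data$prop,
                                      fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = state_palette) +
    ggplot2::labs(x = "Day of year", y = "Proportion of positions",
                  fill = "State") +
    ggplot2::theme_minimal()
}

#' Plot a residency density map
#'
#' @param grid `residency_grid` from [kde2d_map()].
#' @param regions Optional region table from [extract_regions()]; centroids
#'   are marked.
#' @return A ggplot object.
#' @export
plot_residency <- function(grid, regions = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(grid),
                       ggplot2::aes(.data$lon, .data$lat,
                                    fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (°E)", y = "Latitude (°N)",
                  fill = expression(km^-2)) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_point(
      data = regions,
      ggplot2::aes(.data$centroid_lon, .data$centroid_lat),
      inherit.aes = FALSE, colour = "red", shape = 4, size = 2)
  }
  p
}

#' Plot run-length distributions by state
#'
#' @param runs Tibble from [run_lengths()].
#' @return A ggplot object.
#' @export
plot_run_lengths <- function(runs) {
  ggplot2::ggplot(runs, ggplot2::aes(.data$run_length, fill = .data$state)) +
    ggplot2::geom_histogram(binwidth = 1, show.legend = FALSE) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::scale_fill_manual(values = state_palette) +
    ggplot2::labs(x = "Run length (days)", y = "Count") +
    ggplot2::theme_minimal()
}
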