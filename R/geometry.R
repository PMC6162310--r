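#' Great Australian Bight reference point
#'
#' The analysis measures all movement relative to a fixed reference locus in
#' the central Great Australian Bight (GAB) at 32 deg S, 130 deg E. Positions
#' within `radius_km` of this point are classified as inside the GAB.
#'
#' @param lat,lon Reference coordinates in decimal degrees.
#' @param radius_km GAB residency radius in kilometres.
#' @return A list with elements `lat`, `lon`, `radius_km`.
#' @examples
#' gab_reference()
#' @export
gab_reference <- function(lat = -32, lon = 130, radius_km = 500) {
  stopifnot(is.numeric(lat), is.numeric(lon), radius_km > 0)
  check_coords(lat, lon)
  list(lat = lat, lon = lon, radius_km = radius_km)
}

#' Earth radius used throughout (spherical model), km
#' @keywords internal
EARTH_RADIUS_KM <- 6371

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    abort("non-finite coordinate")
  }
  if (any(lat < -90 | lat > 90)) {
    abort("latitude out of range [-90, 90]")
  }
  if (any(lon < -180 | lon > 180)) {
    abort("longitude out of range [-180, 180]")
  }
  invisible(TRUE)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km, vectorised over inputs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(0, 0, 0, 90) # quarter of a great circle, ~10007.5 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Distance to the GAB reference point
#'
#' Adds a `d_gab_km` column: the great-circle distance from each daily
#' position to the GAB reference. This is the distance series whose daily
#' increments drive the behavioural hidden Markov model.
#'
#' @param tracks A track data frame with `fish_id`, `date`, `lat`, `lon`.
#' @param ref A [gab_reference()] list.
#' @return The input as a tibble with an added `d_gab_km` column.
#' @export
add_gab_distance <- function(tracks, ref = gab_reference()) {
  tracks <- tibble::as_tibble(tracks)
  require_cols(tracks, c("fish_id", "date", "lat", "lon"))
  tracks$d_gab_km <- great_circle_km(tracks$lat, tracks$lon, ref$lat, ref$lon)
  tracks
}

#' Daily step observations
#'
#' Computes the signed daily increment of distance to the GAB reference,
#' `d_t = d_GAB(t) - d_GAB(t - 1)`, per fish. Positive values are movement
#' away from the GAB, negative values movement toward it. This signed
#' displacement is the observed variable of the behavioural model; the
#' reporting layer prints inward means as magnitudes.
#'
#' @param tracks Track tibble; `d_gab_km` is computed via [add_gab_distance()]
#'   if absent.
#' @param ref [gab_reference()] used when `d_gab_km` must be computed.
#' @param cap Plausibility cap in km/day; steps with `|d_t| > cap` are flagged
#'   (column `flagged`), not removed.
#' @return Tibble with `fish_id`, `date` (the step's end day), `d_t`,
#'   `flagged`.
#' @export
step_observations <- function(tracks, ref = gab_reference(), cap = 250) {
  tracks <- tibble::as_tibble(tracks)
  if (!"d_gab_km" %in% names(tracks)) {
    tracks <- add_gab_distance(tracks, ref)
  }
  short <- tracks |>
    dplyr::count(.data$fish_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(short) > 0) {
    abort(paste0("tracks with fewer than 2 positions cannot yield steps: ",
                 paste(short$fish_id, collapse = ", ")))
  }
  out <- tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(d_t = c(NA_real_, diff(.data$d_gab_km))) |>
    dplyr::slice(-1) |>
    dplyr::ungroup() |>
    dplyr::select("fish_id", "date", "d_t")
  if (any(!is.finite(out$d_t))) {
    bad <- which(!is.finite(out$d_t))[1]
    abort(paste0("non-finite step observation at row ", bad))
  }
  out$flagged <- abs(out$d_t) > cap
  out
}

#' Cumulative along-track path length
#'
#' Sum of consecutive great-circle step lengths per fish, a descriptive
#' statistic of total distance travelled.
#'
#' @param tracks Track tibble.
#' @return Tibble with `fish_id`, `n_steps`, `path_km`.
#' @export
cumulative_path_length <- function(tracks) {
  tracks <- tibble::as_tibble(tracks)
  require_cols(tracks, c("fish_id", "date", "lat", "lon"))
  tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      n_steps = dplyr::n() - 1L,
      path_km = sum(great_circle_km(
        .data$lat[-dplyr::n()], .data$lon[-dplyr::n()],
        .data$lat[-1], .data$lon[-1])),
      .groups = "drop"
    )
}

require_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
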