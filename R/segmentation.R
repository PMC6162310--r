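#' Classify positions as inside the GAB
#'
#' A position is inside the Great Australian Bight when its distance to the
#' reference point is strictly less than the radius; a position at exactly
#' the radius is outside (declared boundary convention).
#'
#' @param d_gab_km Numeric distance series (km).
#' @param radius Residency radius in km.
#' @return Logical vector, `TRUE` = inside the GAB.
#' @export
classify_gab_residence <- function(d_gab_km, radius = 500) {
  stopifnot(is.numeric(d_gab_km), radius > 0)
  d_gab_km < radius
}

# Maximal out-of-GAB runs of length >= min_run, as positional indices.
out_runs <- function(d_gab_km, radius, min_run) {
  out <- !classify_gab_residence(d_gab_km, radius)
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

#' Segment tracks into trips
#'
#' Divides each track into excursions ("trips") by the distance rule: the
#' departure date is the first day of a consecutive run of at least
#' `min_run` positions with `d_GAB >= radius`, and the return date is the
#' first subsequent day back within the radius. Shorter out-of-GAB runs are
#' not trips. A trip still open when the track ends is censored: its
#' `return_date` and `duration_days` are `NA`.
#'
#' Direction is the sign of the net longitude change (shortest way around)
#' over the first `direction_window` days of the trip: negative = westward.
#'
#' @param tracks Track tibble carrying `d_gab_km` (see [add_gab_distance()]);
#'   computed on the fly when absent.
#' @param radius Residency radius, km.
#' @param min_run Minimum run length, in daily positions, for a departure.
#' @param direction_window Days used to assess trip direction.
#' @param ref [gab_reference()] used if `d_gab_km` must be computed.
#' @return Tibble with one row per trip: `fish_id`, `departure_date`,
#'   `return_date`, `duration_days`, `max_d_gab_km`, `direction`
#'   (`"westward"`/`"eastward"`), `censored`.
#' @export
detect_trips <- function(tracks, radius = 500, min_run = 120,
                         direction_window = 30, ref = gab_reference()) {
  tracks <- tibble::as_tibble(tracks)
  if (!"d_gab_km" %in% names(tracks)) tracks <- add_gab_distance(tracks, ref)
  require_cols(tracks, c("fish_id", "date", "lon", "d_gab_km"))
  empty <- tibble::tibble(
    fish_id = character(), departure_date = as.Date(character()),
    return_date = as.Date(character()), duration_days = integer(),
    max_d_gab_km = numeric(), direction = character(), censored = logical())
  found <- tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      df <- dplyr::arrange(df, .data$date)
      runs <- out_runs(df$d_gab_km, radius, min_run)
      if (nrow(runs) == 0) return(NULL)
      n <- nrow(df)
      purrr::pmap(runs, function(start, end, length) {
        censored <- end == n
        dep <- df$date[start]
        ret <- if (censored) as.Date(NA) else df$date[end + 1L]
        w_end <- min(start + direction_window, end)
        dlon <- lon_diff(df$lon[w_end], df$lon[start])
        tibble::tibble(
          fish_id = df$fish_id[1],
          departure_date = dep,
          return_date = ret,
          duration_days = if (censored) NA_integer_ else
            as.integer(ret - dep),
          max_d_gab_km = max(df$d_gab_km[start:end]),
          direction = if (dlon < 0) "westward" else "eastward",
          censored = censored)
      }) |> purrr::list_rbind()
    }) |>
    purrr::list_rbind()
  if (is.null(found) || nrow(found) == 0) empty else found
}

# shortest-way-around longitude difference, degrees in (-180, 180]
lon_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Descriptive trip statistics
#'
#' Summarises a trip table: duration statistics over complete trips only
#' (a censored trip has no duration), maximum-distance statistics over all
#' trips, and the directional split. With a single complete trip the
#' duration SD is reported as 0 and `n_complete` flags the situation.
#'
#' @param trips Trip tibble from [detect_trips()].
#' @return One-row tibble of summary statistics; with no trips the counts
#'   are zero and the statistics `NA`.
#' @export
trip_summaries <- function(trips) {
  if (is.null(trips) || nrow(trips) == 0) {
    return(tibble::tibble(
      n_trips = 0L, n_complete = 0L,
      duration_mean = NA_real_, duration_sd = NA_real_,
      duration_min = NA_integer_, duration_max = NA_integer_,
      maxdist_mean = NA_real_, maxdist_sd = NA_real_,
      maxdist_max = NA_real_,
      frac_westward = NA_real_, frac_eastward = NA_real_))
  }
  comp <- trips[!trips$censored, , drop = FALSE]
  dur_sd <- if (nrow(comp) >= 2) sd(comp$duration_days) else
    if (nrow(comp) == 1) 0 else NA_real_
  tibble::tibble(
    n_trips = nrow(trips),
    n_complete = nrow(comp),
    duration_mean = if (nrow(comp) > 0) mean(comp$duration_days) else NA_real_,
    duration_sd = dur_sd,
    duration_min = if (nrow(comp) > 0) min(comp$duration_days) else NA_integer_,
    duration_max = if (nrow(comp) > 0) max(comp$duration_days) else NA_integer_,
    maxdist_mean = mean(trips$max_d_gab_km),
    maxdist_sd = if (nrow(trips) >= 2) sd(trips$max_d_gab_km) else 0,
    maxdist_max = max(trips$max_d_gab_km),
    frac_westward = mean(trips$direction == "westward"),
    frac_eastward = mean(trips$direction == "eastward"))
}
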