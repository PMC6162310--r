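#' Read tag tracks from delimited text
#'
#' Reads a CSV of daily geolocation positions into a track tibble with one
#' row per fish-day. Rows whose coordinates or date fail to parse are
#' dropped with a message reporting the count; positions are returned sorted
#' by fish and date.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Named character vector mapping the canonical column names
#'   `fish_id`, `date`, `lat`, `lon` (and optionally `age_at_tagging`) to the
#'   column names used in the file.
#' @return Tibble with columns `fish_id` (character), `date` (Date), `lat`,
#'   `lon` (decimal degrees) and, when present in the file,
#'   `age_at_tagging` (integer years).
#' @export
read_tracks <- function(path,
                        dialect = c(fish_id = "fish_id", date = "date",
                                    lat = "lat", lon = "lon",
                                    age_at_tagging = "age_at_tagging")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("empty track file: ", path))
  src_of <- function(col) {
    if (col %in% names(dialect)) dialect[[col]] else col
  }
  mandatory <- c("fish_id", "date", "lat", "lon")
  for (col in mandatory) {
    if (!src_of(col) %in% names(raw)) {
      abort(paste0("missing mandatory column: ", src_of(col)))
    }
  }
  out <- tibble::tibble(
    fish_id = as.character(raw[[src_of("fish_id")]]),
    date = suppressWarnings(as.Date(raw[[src_of("date")]])),
    lat = suppressWarnings(as.numeric(raw[[src_of("lat")]])),
    lon = suppressWarnings(as.numeric(raw[[src_of("lon")]]))
  )
  age_src <- src_of("age_at_tagging")
  if (age_src %in% names(raw)) {
    out$age_at_tagging <- suppressWarnings(as.integer(raw[[age_src]]))
  }
  bad <- !is.finite(out$lat) | !is.finite(out$lon) | is.na(out$date) |
    out$lat < -90 | out$lat > 90 | out$lon < -180 | out$lon > 180
  if (any(bad)) {
    inform(paste0("dropped ", sum(bad), " row(s) with unparseable or ",
                  "out-of-range coordinates/dates"))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) abort("no parseable rows in track file")
  dplyr::arrange(out, .data$fish_id, .data$date)
}

#' Write tag tracks to CSV
#'
#' Inverse of [read_tracks()]: writes `fish_id,date,lat,lon[,age_at_tagging]`
#' with ISO-8601 dates. Reading the file back reproduces the input tibble
#' field for field.
#'
#' @param tracks Track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  require_cols(tracks, c("fish_id", "date", "lat", "lon"))
  keep <- intersect(c("fish_id", "date", "lat", "lon", "age_at_tagging"),
                    names(tracks))
  readr::write_csv(tracks[keep], path, progress = FALSE)
  invisible(path)
}

#' Regularise tracks to a strict daily time step
#'
#' Downstream behaviour models assume exactly one position per calendar day.
#' Interior gaps of at most `max_gap` days are filled by great-circle
#' interpolation along the shorter arc (so tracks crossing the 180 deg
#' meridian are handled correctly); longer gaps split the track into
#' separate segments whose ids gain a `_s<k>` suffix. The operation is
#' idempotent: a daily track is returned unchanged.
#'
#' @param tracks Track tibble.
#' @param max_gap Largest interior gap, in days, to bridge by interpolation.
#' @return Regularised track tibble, one row per fish-day.
#' @export
regularize_tracks <- function(tracks, max_gap = 5) {
  tracks <- tibble::as_tibble(tracks)
  require_cols(tracks, c("fish_id", "date", "lat", "lon"))
  tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_split() |>
    purrr::map(regularize_one, max_gap = max_gap) |>
    purrr::list_rbind()
}

regularize_one <- function(track, max_gap) {
  track <- dplyr::arrange(track, .data$date)
  if (nrow(track) < 2) {
    abort(paste0("track too short: ", track$fish_id[1]))
  }
  if (anyDuplicated(track$date)) {
    warn(paste0("duplicate dates in track ", track$fish_id[1],
                "; keeping first position of each day"))
    track <- track[!duplicated(track$date), , drop = FALSE]
    if (nrow(track) < 2) abort(paste0("track too short: ", track$fish_id[1]))
  }
  gaps <- as.integer(diff(track$date))
  # split points: gaps wider than max_gap + 1 missing days start a new segment
  seg <- cumsum(c(1L, as.integer(gaps > max_gap + 1L)))
  pieces <- split(seq_len(nrow(track)), seg)
  n_seg <- length(pieces)
  out <- purrr::imap(pieces, function(idx, k) {
    piece <- track[idx, , drop = FALSE]
    if (nrow(piece) < 2) return(NULL) # an isolated position is not a track
    filled <- fill_daily(piece)
    if (n_seg > 1) {
      filled$fish_id <- paste0(filled$fish_id[1], "_s", k)
    }
    filled
  })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    abort(paste0("track too short after splitting: ", track$fish_id[1]))
  }
  purrr::list_rbind(out)
}

fill_daily <- function(piece) {
  gaps <- as.integer(diff(piece$date))
  if (all(gaps == 1L)) return(piece)
  rows <- vector("list", nrow(piece) - 1L)
  for (i in seq_len(nrow(piece) - 1L)) {
    g <- gaps[i]
    seg <- piece[i, , drop = FALSE]
    if (g > 1L) {
      same <- great_circle_km(piece$lat[i], piece$lon[i],
                              piece$lat[i + 1], piece$lon[i + 1]) < 1e-6
      if (same) {
        # a stationary fish: repeat the position (gcIntermediate collapses
        # coincident endpoints)
        mid <- matrix(rep(c(piece$lon[i], piece$lat[i]), each = g - 1L),
                      ncol = 2)
      } else {
        mid <- geosphere::gcIntermediate(
          c(piece$lon[i], piece$lat[i]),
          c(piece$lon[i + 1], piece$lat[i + 1]),
          n = g - 1L, addStartEnd = FALSE)
        mid <- matrix(mid, ncol = 2)
      }
      ins <- piece[rep(i, g - 1L), , drop = FALSE]
      ins$date <- piece$date[i] + seq_len(g - 1L)
      ins$lon <- mid[, 1]
      ins$lat <- mid[, 2]
      seg <- dplyr::bind_rows(seg, ins)
    }
    rows[[i]] <- seg
  }
  dplyr::bind_rows(c(rows, list(piece[nrow(piece), , drop = FALSE])))
}
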