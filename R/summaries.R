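#' State occupancy summary
#'
#' The proportion of time spent in each behavioural state, computed two
#' ways: pooled over all decoded steps (step-weighted; the headline figure)
#' and as the median across fish of per-fish proportions, with the
#' interquartile range across fish. Pooled proportions sum to one.
#'
#' @param decoded Decoded step tibble from [decode_states()].
#' @return Tibble with `state`, `pooled_prop`, `median_prop`, `iqr`,
#'   `n_steps`.
#' @export
state_occupancy <- function(decoded) {
  require_cols(decoded, c("fish_id", "state"))
  per_fish <- decoded |>
    dplyr::count(.data$fish_id, .data$state, .drop = FALSE, name = "n_state") |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::mutate(prop = .data$n_state / sum(.data$n_state)) |>
    dplyr::ungroup()
  per_fish |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n_steps = sum(.data$n_state),
      median_prop = median(.data$prop),
      iqr = IQR(.data$prop),
      .groups = "drop") |>
    dplyr::mutate(pooled_prop = .data$n_steps / sum(.data$n_steps)) |>
    dplyr::select("state", "pooled_prop", "median_prop", "iqr", "n_steps")
}

#' Run lengths of decoded states
#'
#' Lengths of maximal runs of consecutive steps in one state, per fish. Runs
#' truncated by the ends of a track are counted as observed. The run-length
#' mass per state (sum of lengths) equals that state's total step count.
#'
#' @param decoded Decoded step tibble from [decode_states()].
#' @return Tibble with one row per run: `fish_id`, `state`, `run_length`.
#' @export
run_lengths <- function(decoded) {
  require_cols(decoded, c("fish_id", "state"))
  decoded |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      r <- rle(as.character(df$state))
      tibble::tibble(fish_id = df$fish_id[1],
                     state = factor(r$values, levels = levels(df$state)),
                     run_length = r$lengths)
    }) |>
    purrr::list_rbind()
}

#' Time in migration versus maximum distance
#'
#' Per fish, the number of steps decoded into a migratory state (outward or
#' inward) against the maximum distance from the GAB reached, with a
#' least-squares linear trend and a cross-validated smoothing spline.
#'
#' @param decoded Decoded step tibble.
#' @param dist Distance tibble with `fish_id`, `d_gab_km` (see
#'   [add_gab_distance()]).
#' @return Object of class `migration_trend`: list with `data` (tibble
#'   `fish_id`, `migration_days`, `max_d_gab_km`), `lm_fit`, `spline_fit`
#'   (`NULL`, with a warning, when too few distinct distances support a
#'   spline), `slope`.
#' @export
migration_time_vs_max_distance <- function(decoded, dist) {
  require_cols(decoded, c("fish_id", "state"))
  require_cols(dist, c("fish_id", "d_gab_km"))
  mig <- decoded |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(migration_days = sum(.data$state != "resident"),
                     .groups = "drop")
  mx <- dist |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(max_d_gab_km = max(.data$d_gab_km), .groups = "drop")
  data <- dplyr::inner_join(mig, mx, by = "fish_id")
  if (nrow(data) < 3) abort("need at least 3 fish")
  lm_fit <- stats::lm(migration_days ~ max_d_gab_km, data = data)
  spline_fit <- tryCatch(
    stats::smooth.spline(data$max_d_gab_km, data$migration_days, cv = TRUE),
    error = function(e) {
      warn(paste0("smoothing spline not fitted: ", conditionMessage(e)))
      NULL
    })
  structure(list(data = data, lm_fit = lm_fit, spline_fit = spline_fit,
                 slope = unname(stats::coef(lm_fit)[2])),
            class = "migration_trend")
}

#' @export
tidy.migration_trend <- function(x, ...) {
  s <- summary(x$lm_fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Westward extent by age
#'
#' The mean across fish-years of the minimum (western-most) longitude
#' reached, stratified by age. Age within a track-year is the age at tagging
#' plus the number of calendar years elapsed since release (ages advance at
#' 1 January, a declared convention). Fish without an age at tagging are
#' excluded with a warning.
#'
#' @param tracks Track tibble with `age_at_tagging`.
#' @return Tibble with `age`, `mean_min_lon`, `n_fish_years`.
#' @export
westward_extent_by_age <- function(tracks) {
  require_cols(tracks, c("fish_id", "date", "lon"))
  if (!"age_at_tagging" %in% names(tracks)) {
    abort("tracks carry no age_at_tagging column")
  }
  no_age <- unique(tracks$fish_id[is.na(tracks$age_at_tagging)])
  if (length(no_age) > 0) {
    warn(paste0("excluding ", length(no_age), " fish without age at tagging"))
    tracks <- tracks[!tracks$fish_id %in% no_age, , drop = FALSE]
  }
  if (nrow(tracks) == 0) abort("no fish with known age")
  year_of <- function(d) as.integer(format(d, "%Y"))
  tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::mutate(age = .data$age_at_tagging +
                    year_of(.data$date) - year_of(min(.data$date))) |>
    dplyr::group_by(.data$fish_id, .data$age) |>
    dplyr::summarise(min_lon = min(.data$lon), .groups = "drop") |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(mean_min_lon = mean(.data$min_lon),
                     n_fish_years = dplyr::n(), .groups = "drop")
}

#' Outward versus inward movement-rate difference
#'
#' Percent by which the outward emission mean exceeds the inward emission
#' mean in magnitude: `100 * (mu_outward - |mu_inward|) / |mu_inward|`. At
#' the reported state means of 39.02 and 31.08 km/day this is 25.5%, i.e.
#' outward migration legs cover about 25% more distance per day than return
#' legs.
#'
#' @param params A fitted three-state [hmm_params()] (or an `sbt_hmm` fit).
#' @return Percent difference (scalar).
#' @export
outward_inward_ratio <- function(params) {
  if (inherits(params, "sbt_hmm")) params <- params$params
  stopifnot(inherits(params, "hmm_params"))
  if (!all(c("outward", "inward") %in% params$state_labels)) {
    abort("params must label outward and inward states")
  }
  mu_out <- params$means[["outward"]]
  mu_in <- abs(params$means[["inward"]])
  if (mu_in < 1e-6) abort("inward mean is (near) zero; ratio undefined")
  100 * (mu_out - mu_in) / mu_in
}

#' Occupancy and emission table
#'
#' Combines [state_occupancy()] with the fitted emission parameters into one
#' table per behavioural state (proportion of time, IQR across fish, step
#' mean and SD). Emission means are printed as magnitudes, the convention
#' for reporting movement rates per direction.
#'
#' @param fit An `sbt_hmm` fit.
#' @param decoded Decoded step tibble from [decode_states()].
#' @return Tibble with `state`, `proportion`, `iqr`, `mean`, `sd`.
#' @export
occupancy_table <- function(fit, decoded) {
  stopifnot(inherits(fit, "sbt_hmm"))
  occ <- state_occupancy(decoded)
  tibble::tibble(
    state = fit$params$state_labels,
    proportion = occ$pooled_prop[match(fit$params$state_labels, occ$state)],
    iqr = occ$iqr[match(fit$params$state_labels, occ$state)],
    mean = abs(unname(fit$params$means)),
    sd = unname(fit$params$sds))
}
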