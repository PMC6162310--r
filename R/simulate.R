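#' Default generative emission parameters
#'
#' Per-state normal distributions of the daily signed GAB-distance increment
#' (km/day) used as the simulator default: resident mean 0 / SD 14, outward
#' mean 39.02 / SD 21.58, inward mean -31.08 / SD 22.65 (inward movement
#' decreases the distance, hence the negative sign; magnitudes are what the
#' reporting layer prints).
#'
#' @return Named list with `means` and `sds` of length 3.
#' @export
default_emissions <- function() {
  list(means = c(resident = 0, outward = 39.02, inward = -31.08),
       sds = c(resident = 14.00, outward = 21.58, inward = 22.65))
}

#' Build a constrained transition matrix with a target occupancy
#'
#' Solves in closed form for the four free transition probabilities of the
#' constrained three-state model such that the stationary distribution equals
#' `target`, given a pinned resident self-transition probability. The two
#' migratory self-transitions come out equal; detailed balance on the
#' star-shaped transition graph then guarantees the requested stationary law
#' exactly.
#'
#' @param target Length-3 positive probability vector
#'   (resident, outward, inward), summing to one.
#' @param persistence Resident self-transition probability. Must satisfy
#'   `persistence >= 1 - (target[2] + target[3]) / target[1]`; otherwise the
#'   migratory rows would need probabilities above one and an error reports
#'   the feasible interval.
#' @return 3 x 3 transition matrix with the structural zeros of the model.
#' @examples
#' P <- transition_matrix_for_occupancy(c(0.57, 0.25, 0.18), 0.93)
#' stationary_distribution(P)
#' @export
transition_matrix_for_occupancy <- function(target, persistence = 0.93) {
  stopifnot(length(target) == 3)
  if (any(target <= 0) || abs(sum(target) - 1) > 1e-8) {
    abort("target occupancy must be positive and sum to 1")
  }
  lo <- max(0, 1 - (target[2] + target[3]) / target[1])
  if (persistence < lo || persistence >= 1) {
    abort(paste0("infeasible persistence ", format(persistence),
                 " for this occupancy target; feasible interval is [",
                 format(round(lo, 6)), ", 1)"))
  }
  q <- 1 - persistence
  a12 <- q * target[2] / (target[2] + target[3])
  a13 <- q * target[3] / (target[2] + target[3])
  a_mig <- target[1] * q / (target[2] + target[3]) # leave-probability of both migratory states
  constrained_transition(persistence, a12, 1 - a_mig, 1 - a_mig)
}

#' Simulator configuration
#'
#' Defines the generative conditions for synthetic juvenile southern bluefin
#' tuna tag tracks: a population of fish alternating Great Australian Bight
#' residency with east-west migration excursions, driven by the constrained
#' three-state Markov chain and the state-specific step distributions.
#' Defaults follow the study system: 110 fish, state occupancy
#' 0.57/0.25/0.18 with >90% per-step state persistence, the
#' [default_emissions()] step scales, 84% of excursions heading west, and
#' 60% of fish right-censored mid-excursion (tag recapture or failure), so
#' some fish show only one-way migrations.
#'
#' @param n_fish Number of fish.
#' @param n_steps Daily steps per fish before censoring (positions are
#'   `n_steps + 1`).
#' @param params Generative [hmm_params()]; default uses
#'   [transition_matrix_for_occupancy()] at the default occupancy and
#'   [default_emissions()].
#' @param gab [gab_reference()].
#' @param p_westward Probability an excursion heads west.
#' @param bearing_sd_deg SD of the per-excursion bearing about due west/east.
#' @param wander_sd Resident isotropic wander SD, km/day per axis; its radial
#'   component is the resident step observation.
#' @param tangential_sd Small lateral jitter (km/day) during migration so
#'   migratory legs are not perfectly radial.
#' @param tangential_speed Maximum lateral speed (km/day) with which a fish
#'   turns onto a new excursion bearing.
#' @param censor_fraction Fraction of fish truncated mid-excursion.
#' @param start_radius_max Initial distance from the GAB reference is drawn
#'   uniformly on `[0, start_radius_max]` km.
#' @param release_years,release_doy_range Release dates are drawn uniformly
#'   from these calendar years and day-of-year window (tags go out during
#'   the austral summer GAB season).
#' @param ages Ages at tagging to sample from (years).
#' @param seasonal_amplitude If positive, the resident-to-migratory hazard is
#'   modulated over the year by a von Mises bump centred on
#'   `departure_peak_doy` (amplitude 0 keeps the chain time-homogeneous,
#'   which is the default generative model).
#' @param departure_peak_doy Peak departure day-of-year for the seasonal
#'   option.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 110, n_steps = 730,
                       params = NULL, gab = gab_reference(),
                       p_westward = 0.84, bearing_sd_deg = 10,
                       wander_sd = 14, tangential_sd = 5,
                       tangential_speed = 30,
                       censor_fraction = 0.6, start_radius_max = 300,
                       release_years = 1998:2008,
                       release_doy_range = c(1, 90),
                       ages = 1:4,
                       seasonal_amplitude = 0,
                       departure_peak_doy = 147) {
  if (is.null(params)) {
    em <- default_emissions()
    params <- hmm_params(
      transition_matrix_for_occupancy(c(0.57, 0.25, 0.18), 0.93),
      means = unname(em$means), sds = unname(em$sds), constrained = TRUE)
  }
  stopifnot(inherits(params, "hmm_params"),
            p_westward >= 0, p_westward <= 1,
            wander_sd > 0, censor_fraction >= 0, censor_fraction <= 1)
  structure(list(
    n_fish = n_fish, n_steps = n_steps, params = params, gab = gab,
    p_westward = p_westward, bearing_sd_deg = bearing_sd_deg,
    wander_sd = wander_sd, tangential_sd = tangential_sd,
    tangential_speed = tangential_speed,
    censor_fraction = censor_fraction, start_radius_max = start_radius_max,
    release_years = release_years, release_doy_range = release_doy_range,
    ages = ages, seasonal_amplitude = seasonal_amplitude,
    departure_peak_doy = departure_peak_doy), class = "sim_config")
}

#' Simulate a latent state sequence
#'
#' Realises the behavioural Markov chain, starting from the stationary
#' distribution. Forbidden (zero-probability) transitions never occur.
#'
#' @param P Row-stochastic transition matrix.
#' @param n_steps Sequence length.
#' @param seed Optional integer seed (set locally).
#' @return Integer vector of states in `1:nrow(P)`.
#' @export
simulate_states <- function(P, n_steps, seed = NULL) {
  P <- as.matrix(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    abort("invalid transition matrix")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(P)
  # a reducible chain (e.g. the identity) has no unique stationary law;
  # start uniformly in that case
  delta <- tryCatch(stationary_distribution(P),
                    error = function(e) rep(1 / K, K))
  s <- integer(n_steps)
  s[1] <- sample.int(K, 1, prob = delta)
  for (t in seq_len(n_steps - 1L)) {
    s[t + 1L] <- sample.int(K, 1, prob = P[s[t], ])
  }
  s
}

# One step of the time-inhomogeneous (seasonal) variant: the resident row's
# leave probabilities are scaled by a von Mises factor of the current DOY.
seasonal_states <- function(P, doys, amplitude, peak_doy) {
  n <- length(doys)
  s <- integer(n)
  delta <- stationary_distribution(P)
  s[1] <- sample.int(3, 1, prob = delta)
  theta <- 2 * pi * doys / 365.25
  theta0 <- 2 * pi * peak_doy / 365.25
  fac <- exp(amplitude * (cos(theta - theta0) - 1))
  for (t in seq_len(n - 1L)) {
    Pt <- P
    leave <- (P[1, 2] + P[1, 3]) * fac[t]
    Pt[1, ] <- c(1 - leave, leave * P[1, 2] / (P[1, 2] + P[1, 3]),
                 leave * P[1, 3] / (P[1, 2] + P[1, 3]))
    s[t + 1L] <- sample.int(3, 1, prob = Pt[s[t], ])
  }
  s
}

#' Simulate one tag track
#'
#' Generates a daily track whose realised GAB-distance increments are draws
#' from the state-specific normals. Internally the fish is propagated in
#' polar coordinates around the GAB reference: migratory and resident radial
#' increments update the distance directly, lateral (tangential) wander and
#' jitter rotate the bearing without altering it, and each excursion gets a
#' fixed bearing (west with probability `p_westward`) that the fish turns
#' onto at a bounded lateral speed. Positions are then laid down with
#' spherical destination geometry, so recomputing the distance series from
#' the positions reproduces the internal draws.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed yields an identical track.
#' @param fish_id Identifier for the output tibble.
#' @param states Optional forced state sequence (integer, length
#'   `config$n_steps`); by default the latent chain is simulated.
#' @return List with `track` (tibble: fish_id, date, lat, lon,
#'   age_at_tagging), `states` (integer per step) and `d_internal` (the
#'   internal radial increments, km/day).
#' @export
simulate_track <- function(config, seed, fish_id = "F001", states = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_steps
  P <- config$params$transition
  mu <- unname(config$params$means)
  sig <- unname(config$params$sds)
  release <- sample_release_date(config)
  age <- sample(config$ages, 1)
  dates <- release + 0:n
  if (is.null(states)) {
    if (config$seasonal_amplitude > 0) {
      doys <- day_of_year(dates[-length(dates)])
      states <- seasonal_states(P, doys, config$seasonal_amplitude,
                                config$departure_peak_doy)
    } else {
      states <- simulate_states(P, n)
    }
  }
  stopifnot(length(states) == n)
  r <- numeric(n + 1)
  az <- numeric(n + 1)
  r[1] <- runif(1, 0, config$start_radius_max)
  az[1] <- runif(1, 0, 360)
  target_az <- az[1]
  d_internal <- numeric(n)
  prev_state <- 1L
  for (t in seq_len(n)) {
    s <- states[t]
    if (s == 2L && prev_state != 2L) {
      west <- runif(1) < config$p_westward
      target_az <- (if (west) 270 else 90) + rnorm(1, 0, config$bearing_sd_deg)
      target_az <- target_az %% 360
    }
    if (s == 1L) {
      u <- rnorm(1, 0, config$wander_sd)
      v <- rnorm(1, 0, config$wander_sd)
      r_new <- max(r[t] + u, 0.1)
      az_new <- az[t] + deg_per_km(v, r_new)
    } else {
      u <- rnorm(1, mu[s], sig[s])
      v <- rnorm(1, 0, config$tangential_sd)
      r_new <- max(r[t] + u, 0.1)
      gap <- ang_diff(target_az, az[t])
      turn <- sign(gap) * min(abs(gap), deg_per_km(config$tangential_speed, r_new))
      az_new <- az[t] + turn + deg_per_km(v, r_new)
    }
    d_internal[t] <- r_new - r[t]
    r[t + 1] <- r_new
    az[t + 1] <- az_new %% 360
    prev_state <- s
  }
  pos <- geosphere::destPoint(c(config$gab$lon, config$gab$lat),
                              b = az, d = r * 1000,
                              a = EARTH_RADIUS_KM * 1000, f = 0)
  track <- tibble::tibble(
    fish_id = fish_id, date = dates,
    lat = pos[, 2], lon = pos[, 1],
    age_at_tagging = as.integer(age))
  list(track = track, states = states, d_internal = d_internal)
}

deg_per_km <- function(km, radius_km) {
  km / (pi / 180 * max(radius_km, 25))
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  if (d > 180) d <- d - 360
  d
}

sample_release_date <- function(config) {
  yr <- sample(config$release_years, 1)
  doy <- sample(seq(config$release_doy_range[1], config$release_doy_range[2]), 1)
  as.Date(paste0(yr, "-01-01")) + (doy - 1)
}

#' Simulate step-observation series from the behavioural model
#'
#' Draws latent state sequences from the transition matrix (started at its
#' stationary distribution) and observations from the state-conditional
#' normals — the model's own sample space, with no track geometry. This is
#' the appropriate design for validating the estimator itself (parameter
#' and occupancy recovery): track-space simulation necessarily truncates
#' inward displacements once a fish reaches the reference point, which is a
#' property of the geometry, not of the inference.
#'
#' @param params Generative [hmm_params()].
#' @param n_series Number of independent series ("fish").
#' @param n_steps Steps per series.
#' @param seed Integer seed.
#' @return Tibble with `fish_id`, `t`, `d_t`, `true_state`.
#' @export
simulate_step_series <- function(params, n_series, n_steps, seed) {
  stopifnot(inherits(params, "hmm_params"))
  set.seed(seed)
  mu <- unname(params$means); sig <- unname(params$sds)
  purrr::map(seq_len(n_series), function(i) {
    s <- simulate_states(params$transition, n_steps)
    tibble::tibble(fish_id = sprintf("F%03d", i),
                   t = seq_len(n_steps),
                   d_t = rnorm(n_steps, mu[s], sig[s]),
                   true_state = params$state_labels[s])
  }) |> purrr::list_rbind()
}

#' Simulate a tagged population
#'
#' Simulates `n_fish` independent tracks from the configured generative
#' model and right-censors a fraction of them mid-excursion, emulating tag
#' recapture or failure away from the GAB (one-way migrants). All randomness
#' derives from `seed` via per-fish sub-seeds, so the output is reproducible
#' bit for bit.
#'
#' @param config A [sim_config()].
#' @param seed Integer root seed.
#' @return List of class `sbt_sim` with: `tracks` (all fish, one row per
#'   fish-day), `states` (truth table: fish_id, date, true_state, one row per
#'   step), `trips` (true departure/return dates per fish from the
#'   500 km / 120-position rule, `return_date` `NA` when censored), `config`,
#'   `seed`.
#' @export
simulate_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_fish
  if (n == 0) {
    return(structure(list(
      tracks = tibble::tibble(fish_id = character(), date = as.Date(character()),
                              lat = numeric(), lon = numeric(),
                              age_at_tagging = integer()),
      states = tibble::tibble(fish_id = character(), date = as.Date(character()),
                              true_state = character()),
      trips = tibble::tibble(fish_id = character(),
                             departure_date = as.Date(character()),
                             return_date = as.Date(character())),
      config = config, seed = seed), class = "sbt_sim"))
  }
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  censored <- rep(FALSE, n)
  n_cens <- round(config$censor_fraction * n)
  if (n_cens > 0) censored[sample.int(n, n_cens)] <- TRUE
  cens_u <- runif(n)
  labels <- config$params$state_labels
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("F%03d", i)
    sim <- simulate_track(config, seed = sub_seeds[i], fish_id = id)
    track <- sim$track
    states <- sim$states
    if (censored[i]) {
      dser <- great_circle_km(track$lat, track$lon,
                              config$gab$lat, config$gab$lon)
      runs <- out_runs(dser, config$gab$radius_km, min_run = 120)
      if (nrow(runs) > 0) {
        run <- runs[sample.int(nrow(runs), 1), ]
        # truncate at a uniform position inside the excursion
        cut <- run$start + floor(cens_u[i] * (run$end - run$start - 30)) + 30
        cut <- min(max(cut, run$start + 1), run$end)
        track <- track[seq_len(cut), , drop = FALSE]
        states <- states[seq_len(cut - 1L)]
      }
    }
    out[[i]] <- list(
      track = track,
      states = tibble::tibble(fish_id = id, date = track$date[-1],
                              true_state = labels[states])
    )
  }
  tracks <- purrr::list_rbind(purrr::map(out, "track"))
  states_tbl <- purrr::list_rbind(purrr::map(out, "states"))
  trips <- detect_trips(add_gab_distance(tracks, config$gab),
                        radius = config$gab$radius_km, min_run = 120) |>
    dplyr::select("fish_id", "departure_date", "return_date")
  structure(list(tracks = tracks, states = states_tbl, trips = trips,
                 config = config, seed = seed),
            class = "sbt_sim")
}
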