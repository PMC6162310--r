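#' Day of year
#'
#' Calendar day-of-year in 1-366; 29 February maps to 60.
#'
#' @param dates Date vector.
#' @return Integer vector.
#' @export
day_of_year <- function(dates) {
  as.POSIXlt(dates)$yday + 1L
}

doy_to_angle <- function(doy) {
  (2 * pi * doy / 365.25) %% (2 * pi)
}

# von Mises density, numerically stable for large kappa
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Maximum-likelihood concentration from the mean resultant length
# (standard series approximations of the inverse of A(kappa)).
kappa_ml <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Circular kernel density of annual timing
#'
#' Von Mises kernel density estimate of day-of-year events (departures from
#' or returns to the GAB), treating the year as a circle so the Dec 31/Jan 1
#' boundary causes no edge artifact. The kernel concentration defaults to a
#' plug-in rule: the von Mises maximum-likelihood concentration implied by
#' the sample's mean resultant length, sharpened by `n^(2/7)` and capped at
#' 500. The `n^(2/7)` rate is the mode-estimation analogue of the usual
#' density-estimation rate: these densities are read off for their peak
#' days, and mode estimation calls for a smoother bandwidth
#' (`h` of order `n^(-1/7)`) than pointwise density estimation.
#'
#' @param doy Numeric day-of-year values in `[1, 366]`, or a Date vector.
#' @param kappa Kernel concentration (> 0); `NULL` selects the plug-in value.
#' @param grid_doy Evaluation grid; defaults to the 1-day grid `1:366`.
#' @return Object of class `circular_density`: a list with `grid_doy`,
#'   `theta`, `density` (per radian; integrates to one over the circle),
#'   `kappa`, `n`.
#' @export
circular_density <- function(doy, kappa = NULL, grid_doy = 1:366) {
  if (inherits(doy, "Date")) doy <- day_of_year(doy)
  doy <- doy[!is.na(doy)]
  if (length(doy) == 0) abort("empty sample")
  theta_i <- doy_to_angle(doy)
  n <- length(theta_i)
  if (is.null(kappa)) {
    C <- mean(cos(theta_i)); S <- mean(sin(theta_i))
    rbar <- min(sqrt(C^2 + S^2), 1 - 1e-12)
    kappa <- min(kappa_ml(rbar) * n^(2 / 7), 500)
    kappa <- max(kappa, 1e-6)
  }
  if (kappa <= 0) abort("kappa must be positive")
  theta <- doy_to_angle(grid_doy)
  dens <- vapply(theta,
                 function(th) mean(dvonmises(th, theta_i, kappa)),
                 numeric(1))
  structure(list(grid_doy = grid_doy, theta = theta, density = dens,
                 kappa = kappa, n = n),
            class = "circular_density")
}

#' Peak day of a circular density
#'
#' Argmax of the density on its day-of-year grid. Exact ties (a flat
#' density) are broken toward the smallest day with a warning.
#'
#' @param density A `circular_density` object.
#' @return Integer day-of-year of the peak.
#' @export
circular_peak <- function(density) {
  stopifnot(inherits(density, "circular_density"))
  d <- density$density
  if (diff(range(d)) < 1e-9 * max(mean(d), 1e-300)) {
    warn("density is flat; peak day-of-year is tied, returning the smallest")
    return(density$grid_doy[1])
  }
  density$grid_doy[which.max(d)]
}

#' Behavioural state proportions by day of year
#'
#' For each day of year, the fraction of available fish-days decoded into
#' each behavioural state (fractions sum to one within each day), together
#' with the number of fish-days contributing.
#'
#' @param decoded Decoded step tibble from [decode_states()] (needs `date`
#'   and `state`).
#' @return Tibble with `doy`, `state`, `n` (fish-days available that day),
#'   `prop`.
#' @export
state_proportion_by_doy <- function(decoded) {
  require_cols(decoded, c("date", "state"))
  decoded |>
    dplyr::mutate(doy = day_of_year(.data$date)) |>
    dplyr::count(.data$doy, .data$state, .drop = FALSE, name = "n_state") |>
    dplyr::group_by(.data$doy) |>
    dplyr::mutate(n = sum(.data$n_state),
                  prop = ifelse(.data$n > 0, .data$n_state / .data$n, 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n > 0) |>
    dplyr::select("doy", "state", "n", "prop")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler, used to generate synthetic
#' departure/return phenology for validation.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0; 0 gives the circular uniform).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
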