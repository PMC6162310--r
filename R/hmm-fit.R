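emission_logdens <- function(obs, params) {
  K <- length(params$means)
  vapply(seq_len(K),
         function(k) dnorm(obs, params$means[k], params$sds[k], log = TRUE),
         numeric(length(obs)))
}

check_obs <- function(obs) {
  if (!is.numeric(obs) || length(obs) < 1) abort("observations must be a numeric vector")
  if (any(!is.finite(obs))) {
    abort(paste0("non-finite observation at index ", which(!is.finite(obs))[1]))
  }
  invisible(TRUE)
}

#' Forward log-likelihood of a step series
#'
#' Log-likelihood of one observation series under the model, computed with a
#' scaled forward recursion (per-step normalisation plus a per-step shift of
#' the log emission densities), so series of 10^4+ steps do not underflow.
#'
#' @param obs Numeric vector of daily step observations `d_t` (km/day).
#' @param params An [hmm_params()] object.
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(obs, params) {
  stopifnot(inherits(params, "hmm_params"))
  check_obs(obs)
  ld <- matrix(emission_logdens(obs, params), nrow = length(obs))
  m <- apply(ld, 1, max)
  forward_core(exp(ld - m), params$transition, params$initial) + sum(m)
}

#' Posterior state probabilities (forward-backward smoothing)
#'
#' @inheritParams forward_loglik
#' @return A `length(obs)` x K matrix of smoothed state probabilities; rows
#'   sum to one.
#' @export
posterior_probs <- function(obs, params) {
  stopifnot(inherits(params, "hmm_params"))
  check_obs(obs)
  ld <- matrix(emission_logdens(obs, params), nrow = length(obs))
  m <- apply(ld, 1, max)
  fb <- fb_scaled(exp(ld - m), params$transition, params$initial)
  g <- fb$gamma
  colnames(g) <- params$state_labels
  g
}

#' Viterbi decoding of a step series
#'
#' Globally most probable state path given the parameters. Transitions with
#' probability exactly zero (the structural zeros of the constrained model)
#' can never appear on the decoded path.
#'
#' @inheritParams forward_loglik
#' @return Integer vector of state indices (1 = resident, 2 = outward,
#'   3 = inward in the three-state model).
#' @export
viterbi_decode <- function(obs, params) {
  stopifnot(inherits(params, "hmm_params"))
  check_obs(obs)
  ld <- matrix(emission_logdens(obs, params), nrow = length(obs))
  viterbi_core(ld, log(params$transition), log(params$initial))
}

default_init <- function(obs, n_states) {
  s <- max(sd(obs), 1)
  if (n_states == 3) {
    q <- unname(quantile(obs, c(0.1, 0.5, 0.9)))
    means <- c(q[2], max(q[3], q[2] + s / 2), min(q[1], q[2] - s / 2))
    hmm_params(constrained_transition(0.9, 0.05, 0.9, 0.9),
               means = means, sds = rep(s, 3), constrained = TRUE)
  } else if (n_states == 2) {
    q <- unname(quantile(obs, c(0.1, 0.5, 0.9)))
    ext <- if (abs(q[1]) > abs(q[3])) q[1] else q[3]
    if (abs(ext - q[2]) < s / 2) ext <- q[2] + sign(ext - q[2] + 1e-9) * s
    hmm_params(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
               means = c(q[2], ext), sds = rep(s, 2))
  } else {
    abort("n_states must be 2 or 3")
  }
}

relabel_params <- function(params) {
  K <- length(params$means)
  mu <- unname(params$means)
  if (K == 3) {
    out <- which.max(mu); inn <- which.min(mu)
    if (out == inn) return(params)
    res <- setdiff(seq_len(3), c(out, inn))
    perm <- c(res, out, inn)
    labels <- c("resident", "outward", "inward")
  } else if (K == 2) {
    res <- which.min(abs(mu))
    perm <- c(res, setdiff(seq_len(2), res))
    labels <- c("resident", "migratory")
  } else {
    return(params)
  }
  P <- params$transition[perm, perm, drop = FALSE]
  if (params$constrained && (P[2, 3] != 0 || P[3, 2] != 0)) {
    warn("state relabelling moved a structural zero; labels may have drifted during EM")
  }
  hmm_params(P, means = mu[perm], sds = unname(params$sds)[perm],
             initial = unname(params$initial)[perm], state_labels = labels,
             constrained = params$constrained && P[2, 3] == 0 && P[3, 2] == 0)
}

#' Pooled Baum-Welch estimation (low level)
#'
#' Expectation-maximisation over a collection of step series sharing one
#' parameter set. The per-iteration log-likelihood is non-decreasing;
#' transition entries that are exactly zero in `init` (the structural zeros)
#' remain exactly zero throughout. States are relabelled after convergence so
#' that resident has the smallest `|mean|`, outward the most positive mean
#' and inward the most negative.
#'
#' @param obs_list List of numeric step-observation vectors (one per track).
#' @param init Initial [hmm_params()].
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Iteration cap; hitting it returns the best parameters with
#'   `converged = FALSE` and a warning.
#' @param var_floor Lower bound on emission standard deviations (km/day).
#'   Setting it below `1e-3` disables the floor, in which case a collapsing
#'   variance is an error.
#' @param estimate_delta If `TRUE` (default) the initial state distribution
#'   is estimated; otherwise it is reset to the stationary distribution of
#'   the updated transition matrix each iteration.
#' @return List with `params`, `loglik`, `logliks` (trace), `n_iter`,
#'   `converged`.
#' @export
fit_hmm_em <- function(obs_list, init, tol = 1e-8, max_iter = 500,
                       var_floor = 0.1, estimate_delta = TRUE) {
  stopifnot(inherits(init, "hmm_params"), length(obs_list) >= 1)
  purrr::walk(obs_list, check_obs)
  if (any(lengths(obs_list) < 2)) abort("each series must have length >= 2")
  params <- init
  K <- length(params$means)
  logliks <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  obs_all <- unlist(obs_list, use.names = FALSE)
  while (iter < max_iter) {
    iter <- iter + 1L
    xi_tot <- matrix(0, K, K)
    S0 <- numeric(K); S1 <- numeric(K); S2 <- numeric(K)
    gamma1 <- numeric(K)
    ll <- 0
    gammas <- vector("list", length(obs_list))
    for (i in seq_along(obs_list)) {
      obs <- obs_list[[i]]
      ld <- matrix(emission_logdens(obs, params), nrow = length(obs))
      m <- apply(ld, 1, max)
      fb <- fb_scaled(exp(ld - m), params$transition, params$initial)
      ll <- ll + fb$loglik + sum(m)
      xi_tot <- xi_tot + fb$xi
      g <- fb$gamma
      gamma1 <- gamma1 + g[1, ]
      S0 <- S0 + colSums(g)
      S1 <- S1 + colSums(g * obs)
      S2 <- S2 + colSums(g * obs^2)
    }
    logliks <- c(logliks, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    P_new <- params$transition
    rs <- rowSums(xi_tot)
    for (j in seq_len(K)) {
      if (rs[j] > 1e-300) P_new[j, ] <- xi_tot[j, ] / rs[j]
    }
    means <- unname(params$means); sds <- unname(params$sds)
    for (k in seq_len(K)) {
      if (S0[k] > 1e-12) {
        means[k] <- S1[k] / S0[k]
        v <- max(S2[k] / S0[k] - means[k]^2, 0)
        s_new <- sqrt(v)
        if (var_floor >= 1e-3) {
          s_new <- max(s_new, var_floor)
        } else if (s_new < 1e-3) {
          abort(paste0("emission variance collapsed for state ", k,
                       "; provide more data or raise var_floor"))
        }
        sds[k] <- s_new
      }
    }
    delta <- if (estimate_delta) gamma1 / length(obs_list) else
      stationary_distribution(P_new)
    params <- hmm_params(P_new, means, sds, initial = delta,
                         state_labels = params$state_labels,
                         constrained = params$constrained)
  }
  if (!converged) {
    warn(paste0("EM did not converge in ", max_iter,
                " iterations; returning best parameters"))
  }
  list(params = relabel_params(params),
       loglik = logliks[length(logliks)],
       logliks = logliks, n_iter = iter, converged = converged)
}

#' Fit the behaviour-switching model to step observations
#'
#' Pooled (population-level) fit of the constrained three-state model — or
#' the two-state reduction used for fish whose tag ended before any return
#' migration — to a table of daily step observations. All tracks share one
#' parameter set; decoding is per track via [decode_states()].
#'
#' The default initialisation places the state means at the 50%, 90% and 10%
#' quantiles of the pooled observations (resident, outward, inward), uses the
#' pooled standard deviation for all states and self-transition probability
#' 0.9. With `n_restarts > 1`, additional starts jitter the initial means and
#' the best-likelihood solution is kept.
#'
#' @param steps Tibble of step observations, e.g. from [step_observations()].
#' @param n_states 3 (constrained migration model) or 2 (one-way reduction).
#' @param value,id Names of the observation and track-id columns.
#' @param init Optional [hmm_params()] starting point; overrides the default
#'   initialisation (restarts still jitter it).
#' @param n_restarts Number of EM starts.
#' @param tol,max_iter,var_floor,estimate_delta Passed to [fit_hmm_em()].
#' @return An object of class `sbt_hmm` with elements `params`, `loglik`,
#'   `logliks`, `n_iter`, `converged`, `n_obs`, `n_tracks`.
#' @examples
#' sim <- simulate_population(sim_config(n_fish = 5, n_steps = 200), seed = 1)
#' steps <- step_observations(sim$tracks)
#' fit <- fit_hmm(steps, n_restarts = 1, tol = 1e-6)
#' tidy(fit)
#' @export
fit_hmm <- function(steps, n_states = 3, value = "d_t", id = "fish_id",
                    init = NULL, n_restarts = 5, tol = 1e-8, max_iter = 500,
                    var_floor = 0.1, estimate_delta = TRUE) {
  require_cols(steps, c(value, id))
  obs_list <- split(steps[[value]], factor(steps[[id]], unique(steps[[id]])))
  obs_all <- unlist(obs_list, use.names = FALSE)
  base_init <- init %||% default_init(obs_all, n_states)
  best <- NULL
  s <- max(sd(obs_all), 1)
  for (r in seq_len(max(1L, n_restarts))) {
    start <- base_init
    if (r > 1) {
      jitter_means <- unname(base_init$means) + rnorm(n_states, 0, s / 4)
      start <- hmm_params(base_init$transition, jitter_means,
                          unname(base_init$sds),
                          initial = unname(base_init$initial),
                          state_labels = base_init$state_labels,
                          constrained = base_init$constrained)
    }
    fit <- fit_hmm_em(obs_list, start, tol = tol, max_iter = max_iter,
                      var_floor = var_floor, estimate_delta = estimate_delta)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(
    c(best, list(n_obs = length(obs_all), n_tracks = length(obs_list),
                 n_states = n_states)),
    class = "sbt_hmm")
}

#' @rdname fit_hmm
#' @param ... Passed on to [fit_hmm()].
#' @export
fit_two_state <- function(steps, ...) {
  fit_hmm(steps, n_states = 2, ...)
}

#' Decode behavioural states along tracks
#'
#' Per-track Viterbi decoding and forward-backward smoothing under a shared
#' parameter set. Each step is assigned the most probable state of the global
#' best path plus its smoothed posterior probabilities.
#'
#' @param steps Step-observation tibble (see [step_observations()]).
#' @param model An `sbt_hmm` fit or an [hmm_params()] object.
#' @param value,id Column names as in [fit_hmm()].
#' @return `steps` with added columns `state` (factor over the model's state
#'   labels) and one posterior column `p_<label>` per state.
#' @export
decode_states <- function(steps, model, value = "d_t", id = "fish_id") {
  params <- if (inherits(model, "sbt_hmm")) model$params else model
  stopifnot(inherits(params, "hmm_params"))
  require_cols(steps, c(value, id))
  steps <- tibble::as_tibble(steps)
  out <- steps |>
    dplyr::group_by(.data[[id]]) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      obs <- df[[value]]
      path <- viterbi_decode(obs, params)
      post <- posterior_probs(obs, params)
      df$state <- factor(params$state_labels[path],
                         levels = params$state_labels)
      for (k in seq_along(params$state_labels)) {
        df[[paste0("p_", params$state_labels[k])]] <- post[, k]
      }
      df
    }) |>
    purrr::list_rbind()
  out
}

#' @export
print.sbt_hmm <- function(x, ...) {
  cat("Behaviour-switching HMM fit (", x$n_states, " states, pooled over ",
      x$n_tracks, " tracks, ", x$n_obs, " steps)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), "| iterations:", x$n_iter,
      "| converged:", x$converged, "\n\n")
  print(x$params)
  invisible(x)
}

#' @export
tidy.sbt_hmm <- function(x, ...) {
  p <- x$params
  K <- length(p$state_labels)
  trans <- tibble::tibble(
    term = paste0("pi[", rep(p$state_labels, each = K), ",",
                  rep(p$state_labels, K), "]"),
    estimate = as.numeric(t(p$transition))
  )
  emis <- tibble::tibble(
    term = c(paste0("mean[", p$state_labels, "]"),
             paste0("sd[", p$state_labels, "]")),
    estimate = c(unname(p$means), unname(p$sds))
  )
  dplyr::bind_rows(emis, trans)
}

#' @export
glance.sbt_hmm <- function(x, ...) {
  K <- x$n_states
  n_trans <- if (isTRUE(x$params$constrained)) 4L else K * (K - 1L)
  df <- n_trans + 2L * K + (K - 1L)
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * df,
    df = df,
    n_obs = x$n_obs,
    n_tracks = x$n_tracks,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
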