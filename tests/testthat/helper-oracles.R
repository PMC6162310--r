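# Independent brute-force oracles used to validate the HMM recursions.
# These enumerate every state path explicitly and never share code with the
# package's forward-backward / Viterbi implementation.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Enumerates all K^T paths: exact log-likelihood, posterior marginals and
# the most probable path.
enum_oracle <- function(obs, params) {
  K <- length(params$means)
  T_ <- length(obs)
  logdens <- sapply(seq_len(K), function(k) {
    dnorm(obs, params$means[k], params$sds[k], log = TRUE)
  })
  logdens <- matrix(logdens, nrow = T_)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1, function(s) {
    v <- log(unname(params$initial[s[1]])) + logdens[1, s[1]]
    if (T_ > 1) {
      for (t in 2:T_) {
        v <- v + log(params$transition[s[t - 1], s[t]]) + logdens[t, s[t]]
      }
    }
    v
  })
  ll <- logsumexp(lp)
  marg <- matrix(0, T_, K)
  w <- exp(lp - ll)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) marg[t, k] <- sum(w[paths[, t] == k])
  }
  list(loglik = ll,
       marginals = marg,
       best_path = unname(paths[which.max(lp), ]),
       best_logprob = max(lp))
}

# log-probability of a given path under the model (for tie-safe Viterbi checks)
path_logprob <- function(path, obs, params) {
  v <- log(unname(params$initial[path[1]])) +
    dnorm(obs[1], params$means[path[1]], params$sds[path[1]], log = TRUE)
  for (t in seq_along(path)[-1]) {
    v <- v + log(params$transition[path[t - 1], path[t]]) +
      dnorm(obs[t], params$means[path[t]], params$sds[path[t]], log = TRUE)
  }
  unname(v)
}

# Random small model instance; with prob 1/2 a 3-state instance carries the
# structural zeros of the migration model.
random_instance <- function(K = sample(2:3, 1), T_ = sample(2:8, 1),
                            constrained = runif(1) < 0.5) {
  if (K == 3 && constrained) {
    P <- constrained_transition(runif(1, 0.2, 0.9), runif(1, 0.05, 0.1),
                                runif(1, 0.2, 0.9), runif(1, 0.2, 0.9))
  } else {
    P <- matrix(rgamma(K * K, 1), K)
    P <- P / rowSums(P)
  }
  delta <- rgamma(K, 1); delta <- delta / sum(delta)
  params <- hmm_params(P, means = rnorm(K, 0, 20), sds = runif(K, 3, 25),
                       initial = delta)
  obs <- rnorm(T_, 0, 25)
  list(params = params, obs = obs)
}

# Second great-circle formula (spherical law of cosines), independent of the
# haversine implementation.
slc_km <- function(lat1, lon1, lat2, lon2, R = 6371) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  ang <- acos(pmin(pmax(sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl), -1), 1))
  R * ang
}

# Minimal daily track builder for constructed cases.
make_track <- function(lat, lon, fish_id = "T1", start = as.Date("2005-01-01"),
                       age = NULL) {
  tb <- tibble::tibble(fish_id = fish_id,
                       date = start + seq_along(lat) - 1,
                       lat = lat, lon = lon)
  if (!is.null(age)) tb$age_at_tagging <- as.integer(age)
  tb
}
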