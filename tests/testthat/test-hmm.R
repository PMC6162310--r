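test_that("forward log-likelihood matches closed forms and symmetries", {
  # one observation, one-state degenerate model
  p1 <- hmm_params(matrix(1, 1, 1), means = 3, sds = 2, initial = 1,
                   state_labels = "only")
  expect_equal(forward_loglik(5, p1), dnorm(5, 3, 2, log = TRUE),
               tolerance = 1e-12)
  # relabelling symmetry: permuting states leaves the likelihood unchanged
  set.seed(21)
  inst <- random_instance(K = 3, T_ = 6, constrained = FALSE)
  perm <- c(3, 1, 2)
  p <- inst$params
  pperm <- hmm_params(p$transition[perm, perm], unname(p$means)[perm],
                      unname(p$sds)[perm], initial = unname(p$initial)[perm])
  expect_equal(forward_loglik(inst$obs, p), forward_loglik(inst$obs, pperm),
               tolerance = 1e-10)
  expect_error(forward_loglik(c(1, NA, 2), p1), "index 2")
})

test_that("forward, posterior and Viterbi match brute-force enumeration", {
  set.seed(42)
  for (i in 1:50) {
    inst <- random_instance()
    oracle <- enum_oracle(inst$obs, inst$params)
    expect_equal(forward_loglik(inst$obs, inst$params), oracle$loglik,
                 tolerance = 1e-10)
    post <- posterior_probs(inst$obs, inst$params)
    expect_equal(unname(post), oracle$marginals, tolerance = 1e-10)
    expect_equal(rowSums(post), rep(1, length(inst$obs)), tolerance = 1e-12)
    path <- viterbi_decode(inst$obs, inst$params)
    expect_equal(path_logprob(path, inst$obs, inst$params),
                 oracle$best_logprob, tolerance = 1e-10)
    expect_equal(path, oracle$best_path)
  }
})

test_that("single-observation Viterbi maximises delta * density", {
  set.seed(3)
  inst <- random_instance(K = 3, T_ = 1)
  p <- inst$params
  scores <- log(p$initial) +
    dnorm(inst$obs, p$means, p$sds, log = TRUE)
  expect_equal(viterbi_decode(inst$obs, p), unname(which.max(scores)))
})

test_that("Viterbi never uses a forbidden transition and recovers clear states", {
  cfg <- sim_config(n_steps = 400)
  sim <- simulate_track(cfg, seed = 77)
  obs <- step_observations(add_gab_distance(sim$track))$d_t
  path <- viterbi_decode(obs, cfg$params)
  trans <- cbind(path[-length(path)], path[-1])
  expect_false(any(trans[, 1] == 2 & trans[, 2] == 3))
  expect_false(any(trans[, 1] == 3 & trans[, 2] == 2))
  # well-separated emissions: decoded path matches truth on >90% of steps
  expect_gt(mean(path == sim$states), 0.9)
  # data drawn purely from the resident emission decode as all-resident
  set.seed(8)
  calm <- rnorm(300, 0, 14)
  expect_true(all(viterbi_decode(calm, cfg$params) == 1))
})

test_that("stationary distribution satisfies its defining property", {
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(stationary_distribution(P2), c(0.5, 0.5), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    K <- sample(2:3, 1)
    P <- matrix(rgamma(K * K, 1), K); P <- P / rowSums(P)
    pi_ <- stationary_distribution(P)
    expect_equal(as.numeric(pi_ %*% P), pi_, tolerance = 1e-12)
  }
  Pred <- diag(2)
  expect_error(stationary_distribution(Pred), "reducible")
})

test_that("EM log-likelihood is monotone and structural zeros stay exact zeros", {
  cfg <- sim_config(n_fish = 8, n_steps = 250, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 19)
  steps <- step_observations(sim$tracks)
  obs_list <- split(steps$d_t, steps$fish_id)
  fit <- fit_hmm_em(obs_list, cfg$params, tol = 1e-8, max_iter = 200)
  expect_true(all(diff(fit$logliks) > -1e-6 * abs(fit$logliks[-1])))
  expect_identical(fit$params$transition[2, 3], 0)
  expect_identical(fit$params$transition[3, 2], 0)
  # starting at the truth, the first iteration cannot decrease the loglik
  expect_gte(fit$logliks[2], fit$logliks[1])
})

test_that("EM recovers generative parameters on simulated tracks", {
  cfg <- sim_config(n_fish = 25, n_steps = 400, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 4)
  steps <- step_observations(sim$tracks)
  fit <- fit_hmm(steps, n_restarts = 1)
  em <- default_emissions()
  expect_lt(abs(fit$params$means[["outward"]] - em$means[["outward"]]), 2)
  expect_lt(abs(fit$params$means[["inward"]] - em$means[["inward"]]), 2)
  expect_lt(abs(fit$params$sds[["resident"]] - em$sds[["resident"]]), 2)
  expect_lt(abs(fit$params$means[["resident"]]), 2)
  # transition probabilities near the generative matrix
  expect_lt(max(abs(fit$params$transition - cfg$params$transition)), 0.05)
})

test_that("all-zero observations give a resident-dominated solution", {
  obs_list <- list(rep(0, 80), rep(0, 60))
  init <- sim_config()$params
  fit <- suppressWarnings(fit_hmm_em(obs_list, init, max_iter = 100))
  dec <- viterbi_decode(obs_list[[1]], fit$params)
  expect_true(all(dec == 1))
  # variance floor engaged rather than collapsing
  expect_gte(min(fit$params$sds), 0.1)
  expect_error(fit_hmm_em(obs_list, init, max_iter = 100, var_floor = 0),
               "collapsed")
})

test_that("two-state reduction fits one-way migrants and nests in the 3-state model", {
  cfg <- sim_config(n_steps = 300)
  # forced one-way outward tracks: resident spell then permanent departure
  sts <- c(rep(1L, 120), rep(2L, 180))
  obs_list <- lapply(1:6, function(i) {
    sim <- simulate_track(cfg, seed = 100 + i, states = sts)
    step_observations(add_gab_distance(sim$track))$d_t
  })
  steps <- tibble::tibble(
    fish_id = rep(sprintf("F%02d", 1:6), each = length(obs_list[[1]])),
    d_t = unlist(obs_list))
  fit2 <- fit_two_state(steps, n_restarts = 1)
  expect_equal(fit2$n_states, 2)
  expect_lt(abs(fit2$params$means[["migratory"]] -
                default_emissions()$means[["outward"]]), 3)
  # no inward state exists in the decoded output
  dec <- decode_states(steps, fit2)
  expect_setequal(levels(dec$state), c("resident", "migratory"))
  # nesting: the 3-state fit cannot have lower likelihood (the unused inward
  # state may legitimately leave EM wandering without converging)
  fit3 <- suppressWarnings(fit_hmm(steps, n_restarts = 2))
  expect_gte(fit3$loglik, fit2$loglik - 1e-6 * abs(fit2$loglik))
})

test_that("decode_states returns labelled states with coherent posteriors", {
  cfg <- sim_config(n_fish = 3, n_steps = 150, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 31)
  steps <- step_observations(sim$tracks)
  dec <- decode_states(steps, cfg$params)
  expect_equal(nrow(dec), nrow(steps))
  expect_s3_class(dec$state, "factor")
  post_sum <- dec$p_resident + dec$p_outward + dec$p_inward
  expect_equal(post_sum, rep(1, nrow(dec)), tolerance = 1e-9)
})

test_that("fitted parameters serialise to YAML losslessly", {
  fitp <- sim_config()$params
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hmm_params(fitp, path)
  back <- read_hmm_params(path)
  expect_equal(back$transition, fitp$transition, tolerance = 1e-12)
  expect_equal(back$means, fitp$means, tolerance = 1e-12)
  expect_equal(back$sds, fitp$sds, tolerance = 1e-12)
  expect_equal(back$state_labels, fitp$state_labels)
  expect_identical(back$transition[2, 3], 0)
})

test_that("tidy and glance expose the fit in broom form", {
  cfg <- sim_config(n_fish = 4, n_steps = 150, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 12)
  fit <- fit_hmm(step_observations(sim$tracks), n_restarts = 1, tol = 1e-6)
  td <- tidy(fit)
  expect_true(all(c("mean[resident]", "pi[outward,inward]") %in% td$term))
  expect_equal(td$estimate[td$term == "pi[outward,inward]"], 0)
  gl <- glance(fit)
  expect_equal(gl$n_tracks, 4)
  expect_true(gl$logLik < 0)
})
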