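fake_decoded <- function(states_by_fish) {
  purrr::imap(states_by_fish, function(s, id) {
    tibble::tibble(fish_id = id,
                   date = as.Date("2005-01-01") + seq_along(s) - 1,
                   d_t = 0,
                   state = factor(s, levels = c("resident", "outward",
                                                "inward")))
  }) |> purrr::list_rbind()
}

test_that("state occupancy pools and medians correctly", {
  one <- fake_decoded(list(A = rep("resident", 10)))
  occ1 <- state_occupancy(one)
  expect_equal(occ1$pooled_prop[occ1$state == "resident"], 1)
  expect_equal(occ1$iqr[occ1$state == "resident"], 0)
  expect_equal(sum(occ1$pooled_prop), 1, tolerance = 1e-9)
  # equal-length fish, one all-resident one all-outward: pooled 0.5/0.5/0
  two <- fake_decoded(list(A = rep("resident", 10), B = rep("outward", 10)))
  occ2 <- state_occupancy(two)
  expect_equal(occ2$pooled_prop, c(0.5, 0.5, 0))
  # pooled equals the step-count-weighted mean of per-fish proportions
  mixed <- fake_decoded(list(A = rep(c("resident", "outward"), c(30, 10)),
                             B = rep(c("resident", "inward"), c(5, 15))))
  occm <- state_occupancy(mixed)
  w <- c(40, 20) / 60
  manual_res <- w[1] * 30 / 40 + w[2] * 5 / 20
  expect_equal(occm$pooled_prop[occm$state == "resident"], manual_res,
               tolerance = 1e-12)
})

test_that("run lengths partition each decoded track", {
  dec <- fake_decoded(list(A = c("resident", "resident", "resident",
                                 "outward", "outward", "inward")))
  rl <- run_lengths(dec)
  expect_equal(rl$run_length, c(3, 2, 1))
  expect_equal(as.character(rl$state), c("resident", "outward", "inward"))
  single <- fake_decoded(list(B = "resident"))
  expect_equal(run_lengths(single)$run_length, 1)
  # mass conservation on a simulated decoding
  cfg <- sim_config(n_fish = 5, n_steps = 300, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 44)
  dec2 <- decode_states(step_observations(sim$tracks), cfg$params)
  rl2 <- run_lengths(dec2)
  per_state_runs <- rl2 |> dplyr::group_by(state, .drop = FALSE) |>
    dplyr::summarise(mass = sum(run_length), .groups = "drop")
  per_state_steps <- dec2 |> dplyr::count(state, .drop = FALSE)
  expect_equal(as.integer(per_state_runs$mass), per_state_steps$n)
})

test_that("mean run length matches the geometric self-transition law", {
  p <- 0.9
  P <- matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
  s <- simulate_states(P, 40000, seed = 4)
  dec <- tibble::tibble(fish_id = "A",
                        state = factor(c("resident", "outward")[s],
                                       levels = c("resident", "outward",
                                                  "inward")))
  rl <- run_lengths(dec)
  expect_lt(abs(mean(rl$run_length) - 1 / (1 - p)), 0.8)
})

test_that("time-in-migration relates to maximum distance", {
  # collinear synthetic points: slope recovered exactly, spline follows line
  fish <- sprintf("F%02d", 1:8)
  max_d <- seq(1000, 8000, length.out = 8)
  days <- 20 + 0.05 * max_d
  dec <- purrr::map2(fish, days, function(id, k) {
    tibble::tibble(fish_id = id,
                   state = factor(rep(c("outward", "resident"), c(k, 10)),
                                  levels = c("resident", "outward", "inward")))
  }) |> purrr::list_rbind()
  dist <- tibble::tibble(fish_id = rep(fish, each = 2),
                         d_gab_km = as.vector(rbind(0, max_d)))
  tr <- migration_time_vs_max_distance(dec, dist)
  expect_equal(tr$slope, 0.05, tolerance = 1e-6)
  if (!is.null(tr$spline_fit)) {
    pred <- stats::predict(tr$spline_fit, x = max_d)$y
    expect_equal(pred, unname(days), tolerance = 0.1)
  }
  expect_error(migration_time_vs_max_distance(dec[dec$fish_id %in% fish[1:2], ],
                                              dist), "at least 3")
  # zero-slope points: fitted slope CI covers 0
  set.seed(6)
  dec0 <- purrr::map(fish, function(id) {
    tibble::tibble(fish_id = id,
                   state = factor(rep(c("outward", "resident"),
                                      c(50 + sample(-5:5, 1), 10)),
                                  levels = c("resident", "outward", "inward")))
  }) |> purrr::list_rbind()
  tr0 <- migration_time_vs_max_distance(dec0, dist)
  ci <- stats::confint(tr0$lm_fit)["max_d_gab_km", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
  # simulated population: more distant trips mean more migration days
  cfg <- sim_config(n_fish = 20, n_steps = 500, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 15)
  steps <- step_observations(sim$tracks)
  decs <- decode_states(steps, cfg$params)
  trs <- migration_time_vs_max_distance(decs, add_gab_distance(sim$tracks))
  expect_gt(trs$slope, 0)
})

test_that("westward extent decreases with age in an age-stratified population", {
  # constructed: one fish never leaving 130E
  still <- make_track(rep(-32, 400), rep(130, 400), fish_id = "S", age = 2)
  w1 <- westward_extent_by_age(still)
  expect_true(all(w1$mean_min_lon == 130))
  expect_equal(w1$age, c(2, 3)) # crosses one Jan 1
  # a fish reaching 80E in its second calendar year contributes at age+1
  roam <- make_track(rep(-32, 400), c(rep(130, 300), rep(80, 100)),
                     fish_id = "R", start = as.Date("2005-06-01"), age = 1)
  w2 <- westward_extent_by_age(roam)
  expect_equal(w2$mean_min_lon[w2$age == 2], 80)
  # missing ages are excluded with a warning
  noage <- make_track(rep(-32, 10), rep(130, 10), fish_id = "N")
  noage$age_at_tagging <- NA_integer_
  expect_warning(w3 <- westward_extent_by_age(dplyr::bind_rows(still, noage)),
                 "without age")
  expect_equal(sum(w3$n_fish_years), 2) # only the aged fish contributes
  # generative westward drift: older ages reach further west on average
  set.seed(30)
  mk <- function(id, age, west_lon) {
    make_track(rep(-35, 200), c(rep(130, 100), seq(130, west_lon,
                                                   length.out = 100)),
               fish_id = id, age = age)
  }
  pop <- dplyr::bind_rows(mk("A1", 1, 120), mk("A2", 1, 115),
                          mk("B1", 3, 95), mk("B2", 3, 100),
                          mk("C1", 5, 70), mk("C2", 5, 60))
  w4 <- westward_extent_by_age(pop)
  first_year <- w4[w4$age %in% c(1, 3, 5), ]
  expect_true(all(diff(first_year$mean_min_lon) < 0))
})

test_that("the outward/inward emission ratio reproduces the reported contrast", {
  p <- sim_config()$params
  expect_equal(outward_inward_ratio(p), 100 * (39.02 - 31.08) / 31.08,
               tolerance = 1e-12)
  same <- hmm_params(p$transition, c(0, 30, -30), c(14, 20, 20),
                     constrained = TRUE)
  expect_equal(outward_inward_ratio(same), 0)
  dbl <- hmm_params(p$transition, c(0, 60, -30), c(14, 20, 20),
                    constrained = TRUE)
  expect_equal(outward_inward_ratio(dbl), 100)
  degen <- hmm_params(p$transition, c(0, 30, -1e-9), c(14, 20, 20),
                      constrained = TRUE)
  expect_error(outward_inward_ratio(degen), "undefined")
})

test_that("the occupancy table mirrors the reporting layout", {
  cfg <- sim_config(n_fish = 6, n_steps = 250, censor_fraction = 0)
  sim <- simulate_population(cfg, seed = 50)
  steps <- step_observations(sim$tracks)
  fit <- fit_hmm(steps, n_restarts = 1, tol = 1e-6)
  dec <- decode_states(steps, fit)
  tab <- occupancy_table(fit, dec)
  expect_equal(tab$state, c("resident", "outward", "inward"))
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-9)
  expect_true(all(tab$mean >= 0)) # magnitudes printed
})
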