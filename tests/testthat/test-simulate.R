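test_that("sim_config validates its inputs", {
  expect_error(sim_config(), class = "spinpulse_error_config")
  expect_error(sim_config(change_after = 14, seed = 1),
               class = "spinpulse_error_config")
  expect_error(sim_config(tau_effort = -1, seed = 1),
               class = "spinpulse_error_config")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_participants, 214)
  expect_equal(cfg$n_sessions, 14)
  expect_equal(cfg$change_after, 7)
})

test_that("degenerate generator gives identical points, zero spin and pulse", {
  set.seed(1)
  s <- simulate_affect_series(10, mu_theta = 0.7, sigma_theta = 0,
                              mu_d = 5, sigma_d = 0)
  expect_equal(length(unique(round(s$valence, 12))), 1)
  expect_equal(affect_spin(s$valence, s$activation), 0)
  expect_equal(affect_pulse(s$valence, s$activation), 0)
})

test_that("subscale back-fill round-trips composites on clip-free rows", {
  set.seed(2)
  s <- simulate_affect_series(200, sigma_theta = 0.8, mu_d = 6, sigma_d = 2)
  comp <- affect_composites(s[c("pa", "pd", "na", "nd")])
  free <- !s$clipped
  expect_gt(sum(free), 0)
  expect_equal(comp$valence[free], s$valence[free], tolerance = 1e-12)
  expect_equal(comp$activation[free], s$activation[free], tolerance = 1e-12)
  # clipped rows are flagged precisely: unclipped rows have subscales in (1,9)
  raw_pa <- 5 + (s$valence + s$activation) / 4
  expect_equal(s$clipped | raw_pa == s$pa, rep(TRUE, 200))
})

test_that("realized spin matches the generating angular SD", {
  set.seed(3)
  spins <- replicate(500, {
    s <- simulate_affect_series(14, sigma_theta = 0.8, mu_d = 6, sigma_d = 2)
    affect_spin(s$valence, s$activation)
  })
  expect_equal(mean(spins), 0.8, tolerance = 0.05)
})

test_that("cohort anchors are approximated at n = 500", {
  cfg <- sim_config(n_participants = 500, seed = 17)
  set.seed(17)
  persons <- simulate_person_covariates(500, cfg)
  prof <- purrr::map_dfr(seq_len(500), function(i) {
    s <- simulate_affect_series(14, persons$mu_theta[i],
                                persons$sigma_theta[i],
                                persons$mu_d[i], persons$sigma_d[i])
    tibble::tibble(spin = affect_spin(s$valence, s$activation),
                   pulse = affect_pulse(s$valence, s$activation))
  })
  expect_equal(mean(prof$spin), 0.83, tolerance = 0.1)
  expect_equal(mean(prof$pulse), 2.49, tolerance = 0.25)
  # covariates constant within participant by construction (one row each)
  expect_equal(nrow(persons), 500)
  expect_equal(mean(persons$vge), 0, tolerance = 1e-10)
})

test_that("outcome simulation is exact in the noise-free limit", {
  design <- growth_design()
  long <- tidyr::expand_grid(participant_id = c("a", "b"),
                             session_index = 1:14) |>
    dplyr::left_join(design, by = "session_index") |>
    dplyr::mutate(spin = ifelse(participant_id == "a", 0.4, 1.2))
  gamma <- c("(Intercept)" = 5, SA = 0.5, TA = -2, spin = -1,
             "SA:spin" = -0.2)
  y <- simulate_outcomes(long, gamma, tau = 0, sigma = 0)
  manual <- 5 + 0.5 * long$SA - 2 * long$TA - 1 * long$spin -
    0.2 * long$SA * long$spin
  expect_equal(y, manual, tolerance = 1e-12)

  # all-zero coefficients, no noise: identically zero
  y0 <- simulate_outcomes(long, c(SA = 0), tau = 0, sigma = 0)
  expect_equal(y0, rep(0, 28))

  expect_error(simulate_outcomes(long, c(SA = NaN), 0, 0),
               class = "spinpulse_error_config")
  expect_error(simulate_outcomes(long, c(nope = 1), 0, 0),
               class = "spinpulse_error_schema")
})

test_that("trial inversion reproduces session targets", {
  cfg <- sim_config(seed = 5, total_engagements = 400,
                    fixed_engagements = TRUE)
  sessions <- tidyr::expand_grid(participant_id = "p1",
                                 session_index = 1:14) |>
    dplyr::mutate(performance = seq(10, 140, by = 10))
  set.seed(5)
  trials <- simulate_trials(sessions, cfg)
  expect_equal(nrow(trials), 28)
  back <- collapse_sessions(trial_scores(trials))
  expect_equal(back$performance, sessions$performance, tolerance = 0.5)

  # out-of-range target moves to nearest feasible with a warning
  bad <- dplyr::mutate(sessions[1, ], performance = -25)
  expect_warning(tr <- simulate_trials(bad, cfg), "nearest feasible")
  expect_equal(collapse_sessions(trial_scores(tr))$performance, 0,
               tolerance = 0.5)
})

test_that("flatline injection is caught by the exclusion screen", {
  cfg <- sim_config(n_participants = 10, n_flatline_participants = 2,
                    flatline_sessions = 2, seed = 31)
  study <- suppressWarnings(simulate_study(cfg))
  sessions <- collapse_sessions(trial_scores(study$trials))
  screen <- exclusion_screen(sessions)
  flagged <- screen$participant_id[!screen$keep]
  expect_setequal(flagged, study$ground_truth$flatline_ids)
  expect_true(all(screen$reason[!screen$keep] == "flatline"))
})

test_that("generated studies have the right shape and are reproducible", {
  study <- small_study()
  n <- 60
  expect_equal(nrow(study$outcomes), n * 14)
  expect_equal(nrow(study$trials), n * 28)
  expect_equal(nrow(study$affect), n * 14)
  expect_equal(nrow(study$persons), n)
  expect_equal(nrow(study$effort_items), n * 14)

  # identical seed reproduces every table exactly
  again <- suppressWarnings(simulate_study(
    sim_config(n_participants = 60, seed = 404)
  ))
  expect_identical(study$outcomes, again$outcomes)
  expect_identical(study$trials, again$trials)
  expect_identical(study$affect, again$affect)

  # different seed differs
  other <- suppressWarnings(simulate_study(
    sim_config(n_participants = 60, seed = 405)
  ))
  expect_false(identical(study$outcomes$effort, other$outcomes$effort))

  # person covariates are constant within participant in the long table
  per_sd <- study$outcomes |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(v = sd(spin), .groups = "drop")
  expect_true(all(per_sd$v == 0))
})

test_that("realized metrics track the generating person parameters", {
  study <- small_study()
  joined <- dplyr::left_join(study$profiles,
                             study$ground_truth$person_params,
                             by = "participant_id")
  expect_gte(cor(joined$spin, joined$sigma_theta), 0.8)
  expect_gte(cor(joined$pulse, joined$sigma_d), 0.8)
})

test_that("realized pulse increases with the generating extremity SD", {
  set.seed(6)
  grid <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  mean_pulse <- vapply(grid, function(sd_d) {
    mean(replicate(200, {
      s <- simulate_affect_series(14, sigma_theta = 0.6, mu_d = 6,
                                  sigma_d = sd_d)
      affect_pulse(s$valence, s$activation)
    }))
  }, numeric(1))
  expect_equal(cor(mean_pulse, grid, method = "spearman"), 1)
})

test_that("post-change performance drops under default coefficients", {
  study <- small_study()
  means <- study$outcomes |>
    dplyr::group_by(session_index) |>
    dplyr::summarise(m = mean(performance), .groups = "drop")
  expect_lt(means$m[8], means$m[7])
})
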