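# Independent oracles used across test files. These deliberately take the
# naive route (angle space, session-by-session enumeration, OLS) so they
# share no code with the implementation they check.

# circular SD computed in angle space: theta_t = atan2(activation, valence),
# mean resultant length from mean cos/sin.
circular_sd_angle_oracle <- function(valence, activation) {
  theta <- atan2(activation, valence)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  sqrt(-2 * log(rbar))
}

ratio_angle_oracle <- function(valence, activation) {
  theta <- atan2(activation, valence)
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

# enumerate the design codes one session at a time from the verbal rules
design_oracle <- function(n_sessions, change_after) {
  rows <- list()
  for (s in seq_len(n_sessions)) {
    sa <- s - 1
    ta <- if (s > change_after) 1 else 0
    ra <- if (s > change_after + 1) s - change_after - 1 else 0
    sa_capped <- if (sa > change_after - 1) change_after - 1 else sa
    rows[[s]] <- data.frame(
      session_index = s, SA = sa, TA = ta, RA = ra,
      SA2 = sa_capped^2, RA2 = ra^2
    )
  }
  do.call(rbind, rows)
}

# small long dataset with known structure for model tests
make_long_data <- function(n_participants, n_sessions = 14, change_after = 7,
                           gamma = c("(Intercept)" = 5, SA = 0.5, TA = -2,
                                     RA = -0.3, SA2 = -0.05, RA2 = 0.04),
                           tau = 1, sigma = 0.8, seed = 1,
                           extra_person_cols = NULL) {
  set.seed(seed)
  design <- growth_design(n_sessions, change_after)
  long <- tidyr::expand_grid(
    participant_id = sprintf("p%03d", seq_len(n_participants)),
    session_index = seq_len(n_sessions)
  ) |>
    dplyr::left_join(design, by = "session_index")
  if (!is.null(extra_person_cols)) {
    for (nm in names(extra_person_cols)) {
      vals <- extra_person_cols[[nm]]
      long[[nm]] <- vals[match(long$participant_id,
                               sprintf("p%03d", seq_len(n_participants)))]
    }
  }
  long$y <- simulate_outcomes(long, gamma, tau, sigma)
  long
}

# one small simulated study shared across test files (memoised)
.study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.study_cache$small)) {
    # clamping warnings from the trial inverter are expected at this scale
    .study_cache$small <- suppressWarnings(simulate_study(
      sim_config(n_participants = 60, seed = 404)
    ))
  }
  .study_cache$small
}
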