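#' Default generating coefficients for the effort outcome
#'
#' Named fixed-effect vector used by [sim_config()]: the discontinuous time
#' codes, the ten person covariates, and the spin/pulse main effects and
#' time-code interactions, on the raw (uncentered) scales of the study
#' variables. Units: effort scale points (0-10 metric).
#'
#' @return Named numeric vector (names are model-matrix term labels).
#' @export
default_gamma_effort <- function() {
  c(
    "(Intercept)" = 7.90,
    SA = -0.04, TA = 0.98, RA = -0.76, SA2 = -0.04, RA2 = 0.08,
    gender = -0.24, ability = -0.02, vge = 0.19, openness = -0.06,
    conscientiousness = 0.25, extraversion = 0.20, agreeableness = 0.04,
    emotional_stability = 0.14, valence_variability = 0.30,
    activation_variability = -0.25,
    spin = -0.11, pulse = 0.09,
    "SA:spin" = -0.06, "SA:pulse" = -0.05,
    "TA:spin" = -0.54, "TA:pulse" = -0.07,
    "RA:spin" = 0.02, "RA:pulse" = 0.04
  )
}

#' Default generating coefficients for the performance outcome
#'
#' As [default_gamma_effort()] but for the performance score (x100 metric),
#' including the effort main effect and the two- and three-way interactions
#' of spin, pulse and effort with the time codes. The quadratic
#' reacquisition code carries weight 0 (it is dropped from the performance
#' ladder).
#'
#' @return Named numeric vector.
#' @export
default_gamma_performance <- function() {
  c(
    "(Intercept)" = 34.75,
    SA = 5.47, TA = -18.88, RA = -4.66, SA2 = -0.57, RA2 = 0,
    gender = -17.00, ability = 0.85, vge = 5.02, openness = 0.18,
    conscientiousness = 1.30, extraversion = -1.29, agreeableness = -0.96,
    emotional_stability = 0.43, valence_variability = -1.14,
    activation_variability = 1.03,
    spin = -2.83, pulse = -4.23, effort = -0.14,
    "spin:effort" = 0.23, "pulse:effort" = 0.07,
    "SA:spin" = -0.30, "SA:pulse" = 0.36, "SA:effort" = 0.18,
    "TA:spin" = 1.16, "TA:pulse" = -0.59, "TA:effort" = -0.28,
    "RA:spin" = -0.04, "RA:pulse" = -0.56, "RA:effort" = -0.05,
    "SA:spin:effort" = 0.15, "SA:pulse:effort" = 0.01,
    "TA:spin:effort" = -2.20, "TA:pulse:effort" = -0.43,
    "RA:spin:effort" = 0.23, "RA:pulse:effort" = 0.06
  )
}

default_covariate_params <- function() {
  list(
    p_female = 0.416,
    ability = c(mean = 26.79, sd = 4.09),
    openness = c(mean = 6.43, sd = 0.88),
    conscientiousness = c(mean = 6.25, sd = 0.98),
    extraversion = c(mean = 5.60, sd = 1.16),
    agreeableness = c(mean = 6.86, sd = 0.94),
    emotional_stability = c(mean = 5.26, sd = 1.06),
    vge_freq_any = c(mean = 2.92, sd = 1.42),
    vge_freq_fps = c(mean = 2.35, sd = 1.33),
    vge_hours_any = c(mean = 4.61, sd = 6.59),
    vge_hours_fps = c(mean = 2.03, sd = 4.03)
  )
}

#' Configuration for a synthetic study
#'
#' Bundles every knob of the synthetic-study generator. Defaults emulate the
#' study conditions: 214 participants, 14 sessions of 2 trials with the task
#' change after session 7; person-level angular dispersion (spin) anchored
#' at cohort mean 0.83 / SD 0.51 and extremity dispersion (pulse) at
#' 2.49 / 0.94; covariate distributions matched to the cohort descriptives;
#' and outcome coefficients seeded from the fitted growth models (see
#' [default_gamma_effort()], [default_gamma_performance()]).
#'
#' @param n_participants,n_sessions,trials_per_session,change_after Study
#'   dimensions.
#' @param mu_theta_mean,mu_theta_sd Person mean affect direction (radians):
#'   drawn normal.
#' @param sigma_theta_mean,sigma_theta_sd Person angular dispersion: drawn
#'   from a gamma distribution with this mean/SD. With wrapped-normal angles
#'   the generating `sigma_theta` *is* the population circular SD, so
#'   realized spin recovers it directly.
#' @param mu_d_mean,mu_d_sd Person mean affect extremity (composite units).
#' @param sigma_d_mean,sigma_d_sd Person extremity dispersion (drives pulse).
#' @param gamma_effort,gamma_performance Named generating coefficient
#'   vectors; any subset of the default term names is allowed.
#' @param tau_effort,sigma_effort,tau_performance,sigma_performance Random
#'   intercept and residual SDs for the two outcomes.
#' @param covariate_params Person-covariate distribution parameters.
#' @param n_flatline_participants,flatline_sessions Number of injected
#'   flatlining participants and how many of their sessions flatline
#'   (exercises the exclusion screen; default 0, the post-screen sample).
#' @param subscale_baseline Baseline `m` used when back-solving subscale
#'   scores from composites (scale midpoint 5).
#' @param total_engagements Mean kills+deaths per trial for the trial
#'   inverter (Poisson mean), or an exact fixed count if
#'   `fixed_engagements = TRUE`.
#' @param fixed_engagements Use `total_engagements` deterministically.
#' @param seed Integer seed; mandatory, expanded into per-participant
#'   substreams so participant subsets re-simulate identically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 214, n_sessions = 14,
                       trials_per_session = 2, change_after = 7,
                       mu_theta_mean = 0.5, mu_theta_sd = 0.6,
                       sigma_theta_mean = 0.83, sigma_theta_sd = 0.51,
                       mu_d_mean = 6, mu_d_sd = 1.5,
                       sigma_d_mean = 2.49, sigma_d_sd = 0.94,
                       gamma_effort = default_gamma_effort(),
                       gamma_performance = default_gamma_performance(),
                       tau_effort = 1.6, sigma_effort = 1.3,
                       tau_performance = 9, sigma_performance = 10,
                       covariate_params = default_covariate_params(),
                       n_flatline_participants = 0, flatline_sessions = 2,
                       subscale_baseline = 5,
                       total_engagements = 16, fixed_engagements = FALSE,
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` is mandatory (a single integer).",
          class = "spinpulse_error_config")
  }
  if (change_after >= n_sessions || change_after < 1) {
    abort("`change_after` must lie in [1, n_sessions - 1].",
          class = "spinpulse_error_config")
  }
  sds <- c(mu_theta_sd, sigma_theta_sd, mu_d_sd, sigma_d_sd,
           tau_effort, sigma_effort, tau_performance, sigma_performance)
  if (any(sds < 0)) {
    abort("All SD parameters must be nonnegative.",
          class = "spinpulse_error_config")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# truncated-at-zero normal draws via inverse CDF (deterministic in the
# stream: exactly n uniforms consumed)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

# gamma draws parameterized by mean and sd
rgamma_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate one person's circumplex affect series
#'
#' Draws session angles from a wrapped normal (`theta_t = mu_theta +
#' N(0, sigma_theta)`) and extremities from a normal truncated at zero,
#' forms `valence = d * cos(theta)`, `activation = d * sin(theta)`, and
#' back-solves subscale scores `pa = m + (v + a) / 4`, `nd = m - (v + a) / 4`,
#' `pd = m + (v - a) / 4`, `na = m - (v - a) / 4` around the baseline `m`,
#' clipping to the 1-9 response metric. Rows where clipping occurred are
#' flagged (`clipped`); on such rows the subscales no longer reproduce the
#' composites exactly.
#'
#' @param n_sessions Number of sessions to draw.
#' @param mu_theta,sigma_theta Mean direction and angular dispersion
#'   (radians). The population circular SD of the wrapped normal equals
#'   `sigma_theta`.
#' @param mu_d,sigma_d Mean and SD of the extremity (vector length).
#' @param baseline Subscale back-fill baseline (default 5).
#' @return A tibble with `session_index`, `theta`, `distance`, `valence`,
#'   `activation`, `pa`, `pd`, `na`, `nd`, `clipped`.
#' @export
simulate_affect_series <- function(n_sessions = 14, mu_theta = 0.5,
                                   sigma_theta = 0.83, mu_d = 6,
                                   sigma_d = 2.49, baseline = 5) {
  theta <- mu_theta + rnorm(n_sessions, 0, sigma_theta)
  d <- rtnorm0(n_sessions, mu_d, sigma_d)
  v <- d * cos(theta)
  a <- d * sin(theta)
  pa <- baseline + (v + a) / 4
  nd <- baseline - (v + a) / 4
  pd <- baseline + (v - a) / 4
  na_ <- baseline - (v - a) / 4
  clip <- function(x) pmin(pmax(x, 1), 9)
  clipped <- pa != clip(pa) | nd != clip(nd) | pd != clip(pd) |
    na_ != clip(na_)
  tibble(
    session_index = seq_len(n_sessions),
    theta = theta, distance = d, valence = v, activation = a,
    pa = clip(pa), pd = clip(pd), na = clip(na_), nd = clip(nd),
    clipped = clipped
  )
}

#' Simulate the person-level covariate table
#'
#' Draws gender, ability, Big Five scale scores and the four video-game
#' experience items from the configured cohort distributions, computes the
#' standardized experience composite ([vge_composite()]), and draws each
#' person's affect-generating parameters (`mu_theta`, `sigma_theta`, `mu_d`,
#' `sigma_d`) so that cohort mean spin and pulse approximate the configured
#' anchors.
#'
#' @param n Number of participants (>= 2).
#' @param config A [sim_config()].
#' @return A person-level tibble (one row per participant).
#' @export
simulate_person_covariates <- function(n, config) {
  cp <- config$covariate_params
  rn <- function(p) rnorm(n, p["mean"], p["sd"])
  persons <- tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    gender = rbinom(n, 1, cp$p_female),
    ability = rn(cp$ability),
    openness = rn(cp$openness),
    conscientiousness = rn(cp$conscientiousness),
    extraversion = rn(cp$extraversion),
    agreeableness = rn(cp$agreeableness),
    emotional_stability = rn(cp$emotional_stability),
    vge_freq_any = rtnorm0(n, cp$vge_freq_any["mean"], cp$vge_freq_any["sd"]),
    vge_freq_fps = rtnorm0(n, cp$vge_freq_fps["mean"], cp$vge_freq_fps["sd"]),
    vge_hours_any = rtnorm0(n, cp$vge_hours_any["mean"], cp$vge_hours_any["sd"]),
    vge_hours_fps = rtnorm0(n, cp$vge_hours_fps["mean"], cp$vge_hours_fps["sd"]),
    mu_theta = rnorm(n, config$mu_theta_mean, config$mu_theta_sd),
    sigma_theta = rgamma_ms(n, config$sigma_theta_mean, config$sigma_theta_sd),
    mu_d = rtnorm0(n, config$mu_d_mean, config$mu_d_sd),
    sigma_d = rgamma_ms(n, config$sigma_d_mean, config$sigma_d_sd)
  )
  vge_composite(persons)
}

linear_predictor <- function(gamma, data) {
  if (any(!is.finite(gamma))) {
    abort(paste0("Non-finite generating coefficient(s): ",
                 paste(names(gamma)[!is.finite(gamma)], collapse = ", ")),
          class = "spinpulse_error_config")
  }
  terms <- setdiff(names(gamma), "(Intercept)")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  check_model_data(data, vars)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(fml, data = data)
  missing_terms <- setdiff(names(gamma), colnames(mm))
  if (length(missing_terms) > 0) {
    abort(paste0("Predictor term(s) not constructible: ",
                 paste(missing_terms, collapse = ", ")),
          class = "spinpulse_error_config")
  }
  as.numeric(mm[, names(gamma), drop = FALSE] %*% gamma)
}

#' Simulate outcomes from the discontinuous growth model
#'
#' Generates `Y_ij = x_ij' gamma + u_i + e_ij` with `u_i ~ N(0, tau^2)` per
#' participant and `e_ij ~ N(0, sigma^2)` per row, where the design matrix
#' is built from the names of `gamma` (time codes, covariates, and any
#' products written with `:`).
#'
#' @param data Long data frame containing every column referenced by
#'   `names(gamma)` plus `participant_id`.
#' @param gamma Named generating coefficient vector (may include
#'   `"(Intercept)"`).
#' @param tau Random-intercept SD.
#' @param sigma Residual SD.
#' @return Numeric vector of simulated outcomes, one per row of `data`.
#' @export
simulate_outcomes <- function(data, gamma, tau, sigma) {
  pred <- linear_predictor(gamma, data)
  ids <- factor(data$participant_id, levels = unique(data$participant_id))
  u <- rnorm(nlevels(ids), 0, tau)
  pred + u[as.integer(ids)] + rnorm(nrow(data), 0, sigma)
}

#' Invert session performance targets into trial results
#'
#' Draws kills, deaths and finishing place per trial so that the collapsed
#' session scores approximate the target performance values: the rank term
#' absorbs the coarse part of the target and the kill ratio the remainder,
#' with only integer rounding left as error. Targets outside the attainable
#' \[0, 200\] range are moved to the nearest feasible value with a warning.
#'
#' @param sessions Session-level data frame with `participant_id`,
#'   `session_index`, and a `performance` target column.
#' @param config A [sim_config()] (trial count, change point, engagement
#'   intensity).
#' @param flatline_ids Participant ids whose first `config$flatline_sessions`
#'   sessions are emitted as zero-kill/zero-death trials.
#' @return Trial-level tibble: `participant_id`, `trial_index`, `kills`,
#'   `deaths`, `place`, `n_competitors`.
#' @export
simulate_trials <- function(sessions, config, flatline_ids = character(0)) {
  tps <- config$trials_per_session
  n_clamped <- 0L
  rows <- purrr::pmap_dfr(
    sessions[c("participant_id", "session_index", "performance")],
    function(participant_id, session_index, performance) {
      n_comp <- if (session_index <= config$change_after) 3 else 10
      target <- performance
      if (target < 0 || target > 200) {
        n_clamped <<- n_clamped + 1L
        target <- min(max(target, 0), 200)
      }
      flat <- participant_id %in% flatline_ids &&
        session_index <= config$flatline_sessions
      purrr::map_dfr(seq_len(tps), function(k) {
        if (flat) {
          return(tibble(
            participant_id = participant_id,
            trial_index = (session_index - 1L) * tps + k,
            kills = 0L, deaths = 0L, place = n_comp,
            n_competitors = n_comp
          ))
        }
        place <- round(n_comp - (min(target / 200, 1)) * (n_comp - 1))
        place <- min(max(place, 1), n_comp)
        r <- (n_comp - place) / (n_comp - 1)
        kr <- min(max(target / 100 - r, 0), 1)
        total <- if (config$fixed_engagements) config$total_engagements else
          max(1, stats::rpois(1, config$total_engagements))
        kills <- as.integer(round(kr * total))
        tibble(
          participant_id = participant_id,
          trial_index = (session_index - 1L) * tps + k,
          kills = kills, deaths = as.integer(total - kills),
          place = as.integer(place), n_competitors = as.integer(n_comp)
        )
      })
    }
  )
  if (n_clamped > 0) {
    warn(sprintf(
      "%d session target(s) outside [0, 200] moved to the nearest feasible value.",
      n_clamped
    ))
  }
  rows
}

#' Generate a complete synthetic study
#'
#' Runs the full generator: person covariates, per-person circumplex affect
#' series (wrapped-normal angles, truncated-normal extremities), realized
#' affect-variability profiles, effort and performance outcomes following
#' the discontinuous growth model with cross-level interactions, effort
#' items, and trial-level game results inverted from the session
#' performance targets. A single global seed is expanded into
#' per-participant substreams, so re-simulating any subset of participants
#' reproduces their rows exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study`: a list of tibbles
#'   `persons`, `affect`, `profiles`, `outcomes`, `effort_items`, `trials`,
#'   plus `ground_truth` (the full config, person-level generating
#'   parameters and realized random intercepts).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_participants = 8, seed = 42))
#' nrow(study$outcomes) # 8 x 14
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  persons <- simulate_person_covariates(config$n_participants, config)
  person_seeds <- sample.int(.Machine$integer.max - 1, config$n_participants)
  flatline_ids <- head(persons$participant_id, config$n_flatline_participants)
  design <- growth_design(config$n_sessions, config$change_after)

  one_person <- function(i) {
    set.seed(person_seeds[i])
    p <- persons[i, ]
    affect <- simulate_affect_series(
      config$n_sessions, p$mu_theta, p$sigma_theta, p$mu_d, p$sigma_d,
      baseline = config$subscale_baseline
    )
    affect <- mutate(affect, participant_id = p$participant_id,
                     .before = 1)
    profile <- affect_profiles(affect)
    long <- bind_cols(
      p[rep(1, config$n_sessions),
        c("participant_id", "gender", "ability", "vge", "openness",
          "conscientiousness", "extraversion", "agreeableness",
          "emotional_stability")],
      design
    ) |>
      mutate(
        valence_variability = profile$valence_variability,
        activation_variability = profile$activation_variability,
        spin = profile$spin,
        pulse = profile$pulse
      )
    long$effort <- simulate_outcomes(
      long, config$gamma_effort, config$tau_effort, config$sigma_effort
    )
    items <- matrix(
      pmin(pmax(round(rep(long$effort, each = 6) + rnorm(6 * nrow(long), 0, 0.8)), 0), 10),
      ncol = 6, byrow = TRUE
    )
    colnames(items) <- paste0("effort_", 1:6)
    effort_items <- bind_cols(
      long[c("participant_id", "session_index")], as_tibble(items)
    )
    long$performance <- simulate_outcomes(
      long, config$gamma_performance, config$tau_performance,
      config$sigma_performance
    )
    trials <- simulate_trials(
      long[c("participant_id", "session_index", "performance")],
      config, flatline_ids = flatline_ids
    )
    list(affect = affect, profile = profile, long = long,
         effort_items = effort_items, trials = trials)
  }

  parts <- purrr::map(seq_len(config$n_participants), one_person)
  structure(
    list(
      persons = persons,
      affect = purrr::map_dfr(parts, "affect"),
      profiles = purrr::map_dfr(parts, "profile"),
      outcomes = purrr::map_dfr(parts, "long"),
      effort_items = purrr::map_dfr(parts, "effort_items"),
      trials = purrr::map_dfr(parts, "trials"),
      ground_truth = list(
        config = config,
        person_seeds = person_seeds,
        person_params = persons[c("participant_id", "mu_theta",
                                  "sigma_theta", "mu_d", "sigma_d")],
        flatline_ids = flatline_ids
      )
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Synthetic study:",
      nrow(x$persons), "participants,",
      dplyr::n_distinct(x$outcomes$session_index), "sessions,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
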