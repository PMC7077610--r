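person_covariates <- function() {
  c("gender", "ability", "vge", "openness", "conscientiousness",
    "extraversion", "agreeableness", "emotional_stability",
    "valence_variability", "activation_variability")
}

#' Model ladders for the effort and performance outcomes
#'
#' Build the ordered fixed-effect term sets for the stepwise model
#' sequences. Each element is the cumulative term vector for one step.
#'
#' The effort ladder has five steps: (1) the five time codes; (2) + ten
#' person covariates; (3) + spin and pulse main effects; (4) + their
#' interactions with the linear trend SA; (5) + their interactions with the
#' change codes TA and RA. The performance ladder has six: steps 1-3 as
#' above, (4) + the effort main effect, (5) + all two-way interactions of
#' spin, pulse and effort with each other and with SA, TA, RA, and (6) + the
#' spin/pulse x effort x {SA, TA, RA} three-way interactions.
#'
#' @param covariates Person-level covariate columns used from step 2 on.
#' @return A named list of character vectors.
#' @export
effort_ladder <- function(covariates = person_covariates()) {
  s1 <- time_codes()
  s2 <- c(s1, covariates)
  s3 <- c(s2, "spin", "pulse")
  s4 <- c(s3, "SA:spin", "SA:pulse")
  s5 <- c(s4, "TA:spin", "TA:pulse", "RA:spin", "RA:pulse")
  list(model1 = s1, model2 = s2, model3 = s3, model4 = s4, model5 = s5)
}

#' @rdname effort_ladder
#' @export
performance_ladder <- function(covariates = person_covariates()) {
  s1 <- time_codes()
  s2 <- c(s1, covariates)
  s3 <- c(s2, "spin", "pulse")
  s4 <- c(s3, "effort")
  s5 <- c(s4, "spin:effort", "pulse:effort",
          "SA:spin", "SA:pulse", "SA:effort",
          "TA:spin", "TA:pulse", "TA:effort",
          "RA:spin", "RA:pulse", "RA:effort")
  s6 <- c(s5, "SA:spin:effort", "SA:pulse:effort",
          "TA:spin:effort", "TA:pulse:effort",
          "RA:spin:effort", "RA:pulse:effort")
  list(model1 = s1, model2 = s2, model3 = s3, model4 = s4,
       model5 = s5, model6 = s6)
}

#' Fit a stepwise ladder of growth models
#'
#' Refits each step of a model ladder from scratch by maximum likelihood on
#' identical rows and collects a log-likelihood comparison table (higher
#' values indicate better fit). When `prune_ns_quadratic` is `TRUE`
#' (the default for the performance outcome), a quadratic time code
#' (`SA2`/`RA2`) that is non-significant in step 1 at `prune_alpha` is
#' dropped from all subsequent steps.
#'
#' @param data Long data frame with outcome, time codes and covariates.
#' @param outcome Outcome column name.
#' @param steps A named list of cumulative term vectors, e.g.
#'   [effort_ladder()] or [performance_ladder()]; defaults by outcome name.
#' @param prune_ns_quadratic Apply the step-1 quadratic pruning rule.
#' @param prune_alpha Two-tailed significance threshold for pruning.
#' @param center_covariates Passed to [fit_growth_model()].
#' @return An object of class `growth_ladder`: list of `growth_fit`s plus a
#'   `comparison` tibble (`model`, `n_terms`, `logLik`).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_participants = 40, seed = 7))
#' lad <- model_sequence(study$outcomes, "effort",
#'                       steps = effort_ladder()[1:2])
#' lad$comparison
model_sequence <- function(data, outcome,
                           steps = NULL,
                           prune_ns_quadratic = outcome == "performance",
                           prune_alpha = 0.05,
                           center_covariates = FALSE) {
  if (is.null(steps)) {
    steps <- switch(
      outcome,
      effort = effort_ladder(),
      performance = performance_ladder(),
      abort("No default ladder for this outcome; supply `steps`.",
            class = "spinpulse_error_config")
    )
  }
  all_cols <- unique(unlist(strsplit(unlist(steps), ":", fixed = TRUE)))
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Ladder references undefined column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinpulse_error_config")
  }

  fits <- vector("list", length(steps))
  names(fits) <- names(steps)
  dropped <- character(0)
  for (i in seq_along(steps)) {
    terms_i <- setdiff(steps[[i]], dropped)
    fits[[i]] <- fit_growth_model(data, outcome, terms_i,
                                  center_covariates = center_covariates)
    if (i == 1 && prune_ns_quadratic) {
      co <- fits[[1]]$coefficients
      quad <- co$term[co$term %in% c("SA2", "RA2") & co$p.value >= prune_alpha]
      dropped <- quad
    }
  }
  comparison <- purrr::map_dfr(fits, glance, .id = "model") |>
    select("model", "n_terms", "logLik")
  structure(
    list(fits = fits, comparison = comparison, outcome = outcome,
         pruned = dropped),
    class = "growth_ladder"
  )
}

#' @export
print.growth_ladder <- function(x, ...) {
  cat(sprintf("Growth-model ladder for `%s` (%d steps)\n",
              x$outcome, length(x$fits)))
  if (length(x$pruned) > 0) {
    cat("  pruned after step 1:", paste(x$pruned, collapse = ", "), "\n")
  }
  print(x$comparison)
  invisible(x)
}

hypothesis_map <- function() {
  tribble(
    ~hypothesis, ~outcome, ~model, ~term,
    "H1a", "effort", "model3", "spin",
    "H1b", "effort", "model3", "pulse",
    "H2a", "effort", "model4", "SA:spin",
    "H2b", "effort", "model4", "SA:pulse",
    "H3a", "performance", "model5", "spin:effort",
    "H3b", "performance", "model5", "pulse:effort",
    "H4a", "effort", "model5", "TA:spin",
    "H4b", "effort", "model5", "TA:pulse",
    "H5a", "effort", "model5", "RA:spin",
    "H5b", "effort", "model5", "RA:pulse",
    "H6a", "performance", "model6", "TA:spin:effort",
    "H6b", "performance", "model6", "TA:pulse:effort"
  )
}

#' Map the study hypotheses onto fitted ladder terms
#'
#' Collects, for each of the six hypothesis families (a = spin, b = pulse),
#' the estimate of the model term that tests it: H1 spin/pulse main effects
#' on effort; H2 their SA interactions (sustained effort); H3 their effort
#' interactions on performance; H4/H5 their TA/RA interactions on effort
#' (adaptation vs acquisition); H6 the TA/RA three-way interactions with
#' effort on performance. All hypotheses are directional (harmful effects),
#' so a one-tailed p-value in the negative direction is reported alongside
#' the two-tailed one.
#'
#' @param effort_fits A `growth_ladder` for the effort outcome.
#' @param performance_fits A `growth_ladder` for the performance outcome.
#' @return A tibble with one row per hypothesis: `hypothesis`, `outcome`,
#'   `model`, `term`, `estimate`, `std.error`, `statistic`, `df`,
#'   `p.two.tailed`, `p.one.tailed` (directional, negative), `testable`.
#' @export
hypothesis_report <- function(effort_fits, performance_fits) {
  ladders <- list(effort = effort_fits, performance = performance_fits)
  hypothesis_map() |>
    purrr::pmap_dfr(function(hypothesis, outcome, model, term) {
      lad <- ladders[[outcome]]
      row <- NULL
      if (!is.null(lad) && model %in% names(lad$fits)) {
        co <- lad$fits[[model]]$coefficients
        row <- co[co$term == term, ]
      }
      if (is.null(row) || nrow(row) == 0) {
        tibble(
          hypothesis = hypothesis, outcome = outcome, model = model,
          term = term, estimate = NA_real_, std.error = NA_real_,
          statistic = NA_real_, df = NA_real_, p.two.tailed = NA_real_,
          p.one.tailed = NA_real_, testable = FALSE
        )
      } else {
        tibble(
          hypothesis = hypothesis, outcome = outcome, model = model,
          term = term, estimate = row$estimate, std.error = row$std.error,
          statistic = row$statistic, df = row$df,
          p.two.tailed = row$p.value,
          # directional test of a harmful (negative) effect
          p.one.tailed = pt(row$statistic, row$df),
          testable = TRUE
        )
      }
    })
}

#' Substitute emotional stability for spin and pulse in a term set
#'
#' Replaces every term involving `spin` or `pulse` (main effects and
#' products) by the emotional-stability analogue, collapsing the former
#' spin/pulse pairs into single terms. Idempotent on term sets without
#' spin/pulse. Used for the ancillary refits that probe whether affect
#' variability is distinct from emotional stability.
#'
#' @param terms Character vector of fixed-effect terms, or a ladder (named
#'   list of term vectors), in which case each step is substituted.
#' @param drop Trait terms to remove (default spin and pulse).
#' @param add Replacement covariate (default `"emotional_stability"`).
#' @return Same shape as `terms`.
#' @export
#' @examples
#' substitute_covariate(c("SA", "spin", "pulse", "SA:spin", "SA:pulse"))
substitute_covariate <- function(terms, drop = c("spin", "pulse"),
                                 add = "emotional_stability") {
  if (is.list(terms)) {
    return(purrr::map(terms, substitute_covariate, drop = drop, add = add))
  }
  replaced <- vapply(
    strsplit(terms, ":", fixed = TRUE),
    function(parts) {
      if (!any(parts %in% drop)) return(paste(parts, collapse = ":"))
      parts <- ifelse(parts %in% drop, add, parts)
      paste(unique(parts), collapse = ":")
    },
    character(1)
  )
  unique(replaced)
}

#' Predicted trajectories at high and low moderator levels
#'
#' Computes model-implied outcome trajectories across sessions with a
#' person-level moderator set at its mean plus or minus one standard
#' deviation, all other covariates held at their sample means. This is the
#' standard simple-slopes probe of a cross-level interaction.
#'
#' @param fit A `growth_fit` whose terms include at least one product
#'   involving `moderator`.
#' @param moderator Column name of the moderator (e.g. `"spin"`).
#' @param design Optional design tibble ([growth_design()]); defaults to the
#'   sessions present in the fitted data.
#' @param at Numeric multiples of the moderator SD for the levels
#'   (default `c(-1, 1)`).
#' @return A tibble with one row per session per level: `session_index`,
#'   `level` (`"low"`/`"high"` or the SD multiple), `moderator`,
#'   `predicted`.
#' @export
simple_slopes <- function(fit, moderator, design = NULL, at = c(-1, 1)) {
  stopifnot(inherits(fit, "growth_fit"))
  has_interaction <- any(
    vapply(strsplit(fit$terms, ":", fixed = TRUE),
           function(p) length(p) > 1 && moderator %in% p, logical(1))
  )
  if (!has_interaction) {
    abort(sprintf("Fit contains no interaction involving `%s`.", moderator),
          class = "spinpulse_error_config")
  }
  data <- fit$data
  if (is.null(design)) {
    design <- data |>
      distinct(.data$session_index, .data$SA, .data$TA, .data$RA,
               .data$SA2, .data$RA2) |>
      arrange(.data$session_index)
  }
  # person-level columns at their sample means (one value per participant)
  person_vars <- setdiff(
    unique(unlist(strsplit(fit$terms, ":", fixed = TRUE))),
    c(time_codes(), moderator)
  )
  person_means <- purrr::map_dbl(person_vars, function(v) {
    per <- data |> group_by(.data$participant_id) |>
      summarise(x = mean(.data[[v]]), .groups = "drop")
    mean(per$x)
  })
  names(person_means) <- person_vars
  per_mod <- data |> group_by(.data$participant_id) |>
    summarise(x = mean(.data[[moderator]]), .groups = "drop")
  m_mean <- mean(per_mod$x)
  m_sd <- sd(per_mod$x)

  levels_tbl <- tibble(
    sd_multiple = at,
    level = ifelse(at < 0, "low", ifelse(at > 0, "high", "mean")),
    moderator_value = m_mean + at * m_sd
  )
  grid <- tidyr::expand_grid(levels_tbl, design)
  for (v in person_vars) grid[[v]] <- person_means[[v]]
  grid[[moderator]] <- grid$moderator_value

  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  mm <- stats::model.matrix(
    stats::delete.response(stats::terms(fit$formula)), data = grid
  )
  grid$predicted <- as.numeric(mm[, names(beta)] %*% beta)
  grid |>
    select("session_index", "level", moderator = "moderator_value",
           "predicted") |>
    arrange(.data$level, .data$session_index) |>
    structure(class = c("spinpulse_slopes", class(tibble())),
              outcome = fit$outcome, moderator_name = moderator)
}
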