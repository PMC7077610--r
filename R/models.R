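#' The five discontinuous-growth time codes
#' @return Character vector `c("SA", "TA", "RA", "SA2", "RA2")`.
#' @export
time_codes <- function() c("SA", "TA", "RA", "SA2", "RA2")

# A fixed-effect term is a level-1 (within-person) term iff any of its
# factors is a time code; every other term -- person covariates, traits,
# effort, and trait x effort products -- is counted as between-person.
# This single rule reproduces the two-level df bookkeeping of the original
# software for every model in the ladders.
term_is_level1 <- function(term) {
  vapply(
    strsplit(term, ":", fixed = TRUE),
    function(parts) any(parts %in% time_codes()),
    logical(1)
  )
}

#' Degrees of freedom under the two-level counting rule
#'
#' Assigns each fixed-effect term the denominator degrees of freedom of a
#' two-level (observations within participants) random-intercept model:
#' level-1 terms (those involving a time code, alone or in a product) get
#' `n_obs - n_participants - level1_count`; between-person terms get
#' `n_participants - between_count - 1`. The intercept is assigned the
#' level-1 df, matching the convention of standard multilevel software.
#'
#' For the study dimensions (2996 observations, 214 participants) this rule
#' gives, e.g., 2777 for the five time codes alone, 203 with ten person
#' covariates, and 200 when effort joins twelve other between-person terms.
#'
#' @param terms Character vector of fixed-effect term labels (products
#'   written with `:`), excluding the intercept.
#' @param n_obs,n_participants Data dimensions.
#' @return A tibble with `term`, `level` (`"level1"`/`"between"`) and `df`
#'   (the intercept row is included first).
#' @export
#' @examples
#' assign_df(c("SA", "TA", "RA", "SA2", "RA2"), 2996, 214)
assign_df <- function(terms, n_obs, n_participants) {
  lvl1 <- term_is_level1(terms)
  df_l1 <- n_obs - n_participants - sum(lvl1)
  df_btw <- n_participants - sum(!lvl1) - 1
  if (df_l1 <= 0 || df_btw <= 0) {
    abort(
      sprintf(
        "Design too rich: level-1 df = %d, between df = %d.", df_l1, df_btw
      ),
      class = "spinpulse_error_design"
    )
  }
  tibble(
    term = c("(Intercept)", terms),
    level = c("level1", ifelse(lvl1, "level1", "between")),
    df = c(df_l1, ifelse(lvl1, df_l1, df_btw))
  )
}

check_model_data <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Model term(s) reference missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinpulse_error_schema")
  }
  for (v in vars) {
    bad <- !is.finite(data[[v]])
    if (any(bad)) {
      who <- unique(data$participant_id[bad])
      abort(
        sprintf(
          "Non-finite values in `%s` for participant(s): %s. Refusing to fit.",
          v, paste(head(who, 5), collapse = ", ")
        ),
        class = "spinpulse_error_nonfinite"
      )
    }
  }
  invisible(data)
}

#' Fit one discontinuous mixed-effects growth model
#'
#' Fits a linear mixed model with the given fixed-effect terms and a
#' participant random intercept by maximum likelihood (so log-likelihoods
#' are comparable across fixed-effect ladders), then attaches t statistics
#' and p-values using the two-level df rule of [assign_df()].
#'
#' @param data Long data frame with `participant_id`, the outcome column and
#'   every column referenced by `terms`. All model variables must be finite;
#'   an infinite spin sentinel (from a participant whose affect directions
#'   cancel) is refused with an error naming the participants.
#' @param outcome Name of the outcome column (e.g. `"effort"`).
#' @param terms Character vector of fixed-effect terms; products written
#'   with `:` (e.g. `"SA:spin"`).
#' @param center_covariates If `TRUE`, z-scores every person-level
#'   (between) main-effect column before fitting; recorded in the result.
#' @return An object of class `growth_fit`: a list with a `coefficients`
#'   tibble (`term`, `estimate`, `std.error`, `statistic`, `df`, `p.value`,
#'   `level`), variance components `tau2` (random intercept) and `sigma2`
#'   (residual), `logLik`, `n_obs`, `n_participants`, the model `formula`,
#'   and the underlying `nlme::lme` fit as `$fit`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_participants = 30, seed = 1))
#' fit_growth_model(study$outcomes, "effort", time_codes())
fit_growth_model <- function(data, outcome, terms,
                             center_covariates = FALSE) {
  data <- as_tibble(data)
  vars <- unique(c(outcome, unlist(strsplit(terms, ":", fixed = TRUE))))
  if (!"participant_id" %in% names(data)) {
    abort("`data` must have a `participant_id` column.",
          class = "spinpulse_error_schema")
  }
  check_model_data(data, vars)

  centered <- character(0)
  if (center_covariates) {
    btw_mains <- terms[!term_is_level1(terms) & !grepl(":", terms)]
    for (v in btw_mains) {
      s <- sd(data[[v]])
      if (s > 0) {
        data[[v]] <- (data[[v]] - mean(data[[v]])) / s
        centered <- c(centered, v)
      }
    }
  }

  fml <- stats::as.formula(
    paste(outcome, "~", paste(terms, collapse = " + "))
  )
  fit <- tryCatch(
    nlme::lme(
      fixed = fml,
      random = ~ 1 | participant_id,
      data = data,
      method = "ML",
      control = nlme::lmeControl(maxIter = 500, msMaxIter = 500,
                                 tolerance = 1e-8, returnObject = FALSE)
    ),
    error = function(e) {
      abort(
        paste0("Mixed-model fit failed (singular or non-convergent): ",
               conditionMessage(e)),
        class = "spinpulse_error_fit"
      )
    }
  )

  tt <- summary(fit)$tTable
  n_obs <- nrow(data)
  n_part <- dplyr::n_distinct(data$participant_id)
  dfs <- assign_df(terms, n_obs, n_part)
  est <- tibble(
    term = rownames(tt),
    estimate = unname(tt[, "Value"]),
    std.error = unname(tt[, "Std.Error"])
  ) |>
    left_join(dfs, by = "term") |>
    mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pt(-abs(.data$statistic), .data$df)
    ) |>
    select("term", "estimate", "std.error", "statistic", "df",
           "p.value", "level")

  vc <- nlme::VarCorr(fit)
  structure(
    list(
      coefficients = est,
      tau2 = as.numeric(vc["(Intercept)", "Variance"]),
      sigma2 = fit$sigma^2,
      logLik = as.numeric(stats::logLik(fit)),
      n_obs = n_obs,
      n_participants = n_part,
      outcome = outcome,
      terms = terms,
      formula = fml,
      centered = centered,
      data = data,
      fit = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Discontinuous growth model (ML, random participant intercept)\n")
  cat(sprintf("  outcome: %s | %d obs, %d participants\n",
              x$outcome, x$n_obs, x$n_participants))
  cat(sprintf("  logLik %.2f | tau^2 %.3f | sigma^2 %.3f\n",
              x$logLik, x$tau2, x$sigma2))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a growth-model fit
#'
#' @param x A `growth_fit` object.
#' @param one_tailed If `TRUE`, adds `p.one.tailed`, the one-tailed p-value
#'   in the direction of each estimate's sign.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, one_tailed = FALSE, ...) {
  out <- x$coefficients
  if (one_tailed) out <- mutate(out, p.one.tailed = .data$p.value / 2)
  out
}

#' One-row summary of a growth-model fit
#'
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `tau2`, `sigma2`, `n_obs`,
#'   `n_participants`, `n_terms`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik, tau2 = x$tau2, sigma2 = x$sigma2,
    n_obs = x$n_obs, n_participants = x$n_participants,
    n_terms = length(x$terms)
  )
}
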