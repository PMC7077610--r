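#' PANAS-style item map for the four circumplex subscales
#'
#' Returns the default mapping from the 16 affect adjectives to the four
#' circumplex subscales: positive-activating (`pa`: enthusiastic, excited,
#' happy), positive-deactivating (`pd`: at_ease, calm, relaxed),
#' negative-activating (`na`: angry, anxious, frustrated, irritated, tense,
#' uneasy) and negative-deactivating (`nd`: bored, disappointed, discouraged,
#' fatigued). Items are rated 1-9.
#'
#' @return Named list of four character vectors (`pa`, `pd`, `na`, `nd`).
#' @export
#' @examples
#' panas_items()
panas_items <- function() {
  list(
    pa = c("enthusiastic", "excited", "happy"),
    pd = c("at_ease", "calm", "relaxed"),
    na = c("angry", "anxious", "frustrated", "irritated", "tense", "uneasy"),
    nd = c("bored", "disappointed", "discouraged", "fatigued")
  )
}

#' Score affect items into circumplex subscales
#'
#' Aggregates the 16 per-session item ratings into the four subscale scores
#' `pa`, `pd`, `na`, `nd`. By default each subscale is the mean of its items,
#' keeping all subscales on the 1-9 response metric (set `aggregate = "sum"`
#' for item sums).
#'
#' @param data A data frame with one row per participant-session containing
#'   all 16 item columns named as in [panas_items()] (or as in `items`).
#' @param items Named list mapping subscale names to item column names.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @param id_cols Identifier columns carried through to the output.
#' @return A tibble with the id columns plus `pa`, `pd`, `na`, `nd`.
#' @export
#' @examples
#' d <- tibble::tibble(participant_id = "p1", session_index = 1)
#' for (it in unlist(panas_items())) d[[it]] <- 5
#' score_affect_items(d)
score_affect_items <- function(data, items = panas_items(),
                               aggregate = c("mean", "sum"),
                               id_cols = intersect(
                                 c("participant_id", "session_index"),
                                 names(data))) {
  aggregate <- match.arg(aggregate)
  expected <- unlist(items, use.names = FALSE)
  missing_items <- setdiff(expected, names(data))
  if (length(missing_items) > 0) {
    abort(
      paste0("Missing affect item column(s): ",
             paste(missing_items, collapse = ", ")),
      class = "spinpulse_error_schema"
    )
  }
  ratings <- as.matrix(data[expected])
  if (!is.numeric(ratings)) {
    abort("Affect item columns must be numeric.",
          class = "spinpulse_error_validation")
  }
  bad <- !is.na(ratings) & (ratings < 1 | ratings > 9)
  if (any(bad)) {
    abort(
      sprintf("%d affect item rating(s) outside [1, 9].", sum(bad)),
      class = "spinpulse_error_validation"
    )
  }
  agg <- if (aggregate == "mean") rowMeans else rowSums
  out <- as_tibble(data[id_cols])
  for (sub in names(items)) {
    out[[sub]] <- agg(as.matrix(data[items[[sub]]]))
  }
  out
}

#' Compute valence and activation composites
#'
#' Adds the two circumplex composites to a table of subscale scores:
#' `valence = (pa + pd) - (na + nd)` and `activation = (pa + na) - (pd + nd)`.
#' Under subscale-mean scoring both composites lie in \[-16, 16\].
#'
#' @param data A data frame with columns `pa`, `pd`, `na`, `nd`.
#' @return `data` as a tibble with `valence` and `activation` appended.
#' @export
#' @examples
#' affect_composites(tibble::tibble(pa = 9, pd = 9, na = 1, nd = 1))
affect_composites <- function(data) {
  need <- c("pa", "pd", "na", "nd")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing subscale column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinpulse_error_schema")
  }
  as_tibble(data) |>
    mutate(
      valence = (.data$pa + .data$pd) - (.data$na + .data$nd),
      activation = (.data$pa + .data$na) - (.data$pd + .data$nd)
    )
}

# Drop points at the exact origin (undefined direction); returns list with
# the usable unit-vector components and bookkeeping counts.
unit_vectors <- function(valence, activation) {
  stopifnot(length(valence) == length(activation))
  ok <- !is.na(valence) & !is.na(activation)
  valence <- valence[ok]
  activation <- activation[ok]
  d <- sqrt(valence^2 + activation^2)
  degenerate <- d == 0
  list(
    ux = valence[!degenerate] / d[!degenerate],
    uy = activation[!degenerate] / d[!degenerate],
    n_used = sum(!degenerate),
    n_degenerate = sum(degenerate)
  )
}

insufficient_data <- function(what, n_used, n_degenerate) {
  abort(
    sprintf(
      "Cannot compute %s: %d usable point(s) (%d degenerate dropped); need at least 2.",
      what, n_used, n_degenerate
    ),
    class = "spinpulse_error_insufficient_data",
    n_used = n_used, n_degenerate = n_degenerate
  )
}

#' Mean resultant length ratio of affect directions
#'
#' Normalizes each (valence, activation) point to its unit vector, sums the
#' unit vectors, and divides the Euclidean length of the resultant by the
#' number of contributing points. The ratio is 1 when every report shares one
#' direction and approaches 0 when directions cancel. Points at the exact
#' origin have no direction and are excluded.
#'
#' @param valence,activation Numeric vectors of composite scores, one entry
#'   per session.
#' @return A single value in \[0, 1\].
#' @export
#' @examples
#' resultant_length_ratio(c(3, 3, 3), c(4, 4, 4)) # 1
#' resultant_length_ratio(c(1, -1), c(0, 0))      # 0
resultant_length_ratio <- function(valence, activation) {
  u <- unit_vectors(valence, activation)
  if (u$n_used < 2) {
    insufficient_data("resultant length ratio", u$n_used, u$n_degenerate)
  }
  r <- sqrt(sum(u$ux)^2 + sum(u$uy)^2) / u$n_used
  # unit-vector normalization leaves O(1e-16) noise; snap to the closed
  # upper bound so "ratio = 1 iff zero angular variability" holds exactly
  if (1 - r < 1e-12) r <- 1
  min(max(r, 0), 1)
}

#' Affect spin: circular standard deviation of affect directions
#'
#' Spin quantifies how much a person moves between different angles of the
#' affect circumplex across repeated reports. The default variant is the
#' circular standard deviation `sqrt(-2 * log(r))` of the mean resultant
#' length ratio `r`; `variant = "neg2log"` returns `-2 * log(r)` without the
#' square root. Spin is 0 when all reports share a direction and `Inf` when
#' directions cancel completely (`r = 0`).
#'
#' @inheritParams resultant_length_ratio
#' @param variant `"circular_sd"` (default) or `"neg2log"`.
#' @return A single nonnegative value, possibly `Inf`.
#' @export
#' @examples
#' affect_spin(c(3, 3, 3), c(4, 4, 4)) # 0
#' affect_spin(c(1, 0), c(0, 1))       # sqrt(-2 * log(sqrt(2) / 2))
affect_spin <- function(valence, activation,
                        variant = c("circular_sd", "neg2log")) {
  variant <- match.arg(variant)
  r <- resultant_length_ratio(valence, activation)
  spin_from_ratio(r, variant)
}

spin_from_ratio <- function(r, variant = c("circular_sd", "neg2log")) {
  variant <- match.arg(variant)
  if (r == 0) return(Inf)
  # unit-vector normalization leaves O(1e-16) noise in the ratio; angular
  # variance below 1e-12 is indistinguishable from zero in double precision
  if (1 - r < 1e-12) return(0)
  v <- -2 * log(r)
  if (variant == "circular_sd") sqrt(v) else v
}

#' Affect pulse: standard deviation of affect intensities
#'
#' Pulse is the within-person standard deviation of the distances of the
#' repeated (valence, activation) reports from the neutral origin,
#' `sqrt(valence^2 + activation^2)`, irrespective of direction. Origin points
#' contribute a distance of 0 (unlike spin, which must drop them).
#'
#' @inheritParams resultant_length_ratio
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A single nonnegative value.
#' @export
#' @examples
#' affect_pulse(c(3, 0, -3), c(4, 5, -4)) # sd(c(5, 5, 5)) = 0
affect_pulse <- function(valence, activation,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(valence) & !is.na(activation)
  d <- sqrt(valence[ok]^2 + activation[ok]^2)
  if (length(d) < 2) insufficient_data("pulse", length(d), 0L)
  sd_of(d, sd_type)
}

sd_of <- function(x, sd_type) {
  if (sd_type == "sample") sd(x) else sd(x) * sqrt((length(x) - 1) / length(x))
}

#' Uni-dimensional affect variability
#'
#' Within-person standard deviations of the valence and activation composite
#' series taken separately, the uni-dimensional analogues of spin and pulse.
#'
#' @inheritParams affect_pulse
#' @return A named list with `valence_variability` and `activation_variability`.
#' @export
affect_variability <- function(valence, activation,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(valence) & !is.na(activation)
  if (sum(ok) < 2) insufficient_data("uni-dimensional variability", sum(ok), 0L)
  list(
    valence_variability = sd_of(valence[ok], sd_type),
    activation_variability = sd_of(activation[ok], sd_type)
  )
}

#' Per-person affect variability profiles
#'
#' Collapses a long table of per-session composites into one row per
#' participant: mean valence/activation, the uni-dimensional variabilities,
#' the mean resultant length ratio, spin, pulse, and bookkeeping counts
#' (`n_sessions_used`, and `n_degenerate_dropped` origin points excluded from
#' spin). If `data` lacks `valence`/`activation` but has the four subscale
#' columns, composites are computed first via [affect_composites()].
#'
#' @param data Long data frame with `participant_id` and either
#'   `valence`/`activation` or `pa`/`pd`/`na`/`nd` columns.
#' @param spin_variant Passed to [affect_spin()].
#' @param sd_type Passed to [affect_pulse()] and [affect_variability()].
#' @return A tibble with one row per participant.
#' @export
#' @examples
#' d <- tidyr::expand_grid(participant_id = c("a", "b"), session_index = 1:3)
#' d$valence <- c(1, 2, 3, 4, 4, 4)
#' d$activation <- c(3, 2, 1, 0, 0, 0)
#' affect_profiles(d)
affect_profiles <- function(data,
                            spin_variant = c("circular_sd", "neg2log"),
                            sd_type = c("sample", "population")) {
  spin_variant <- match.arg(spin_variant)
  sd_type <- match.arg(sd_type)
  if (!"participant_id" %in% names(data)) {
    abort("`data` must have a `participant_id` column.",
          class = "spinpulse_error_schema")
  }
  if (!all(c("valence", "activation") %in% names(data))) {
    data <- affect_composites(data)
  }
  one <- function(d, id) {
    u <- unit_vectors(d$valence, d$activation)
    if (u$n_used < 2) {
      abort(
        sprintf(
          "Participant %s: %d usable session(s) (%d degenerate); cannot compute spin.",
          id, u$n_used, u$n_degenerate
        ),
        class = "spinpulse_error_insufficient_data"
      )
    }
    r <- sqrt(sum(u$ux)^2 + sum(u$uy)^2) / u$n_used
    if (1 - r < 1e-12) r <- 1
    r <- min(max(r, 0), 1)
    uv <- affect_variability(d$valence, d$activation, sd_type)
    tibble(
      n_sessions_used = sum(!is.na(d$valence) & !is.na(d$activation)),
      n_degenerate_dropped = u$n_degenerate,
      mean_valence = mean(d$valence, na.rm = TRUE),
      mean_activation = mean(d$activation, na.rm = TRUE),
      valence_variability = uv$valence_variability,
      activation_variability = uv$activation_variability,
      resultant_length_ratio = r,
      spin = spin_from_ratio(r, spin_variant),
      pulse = affect_pulse(d$valence, d$activation, sd_type)
    )
  }
  as_tibble(data) |>
    group_by(.data$participant_id) |>
    group_modify(~ one(.x, .y$participant_id)) |>
    ungroup()
}
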