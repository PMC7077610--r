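make_item_row <- function(values) {
  d <- tibble::tibble(participant_id = "p1", session_index = 1L)
  for (it in unlist(panas_items())) d[[it]] <- 5
  for (nm in names(values)) d[[nm]] <- values[[nm]]
  d
}

test_that("subscale scoring averages items and validates input", {
  # constant input
  s <- score_affect_items(make_item_row(list()))
  expect_equal(unlist(s[c("pa", "pd", "na", "nd")]),
               c(pa = 5, pd = 5, na = 5, nd = 5))

  # block-constant input
  d <- make_item_row(setNames(as.list(rep(1, 13)),
                              unlist(panas_items()[c("pd", "na", "nd")])))
  for (it in panas_items()$pa) d[[it]] <- 9
  s <- score_affect_items(d)
  expect_equal(unlist(s[c("pa", "pd", "na", "nd")]),
               c(pa = 9, pd = 1, na = 1, nd = 1))

  # mean oracle on the six negative-activating items
  d <- make_item_row(setNames(as.list(1:6), panas_items()$na))
  expect_equal(score_affect_items(d)$na, mean(1:6))

  # item sums supported as the configurable alternative
  expect_equal(score_affect_items(make_item_row(list()),
                                  aggregate = "sum")$na, 30)

  # schema and range errors
  expect_error(score_affect_items(make_item_row(list())[-3]),
               class = "spinpulse_error_schema")
  expect_error(score_affect_items(make_item_row(list(happy = 11))),
               class = "spinpulse_error_validation")
  expect_error(score_affect_items(make_item_row(list(calm = 0))),
               class = "spinpulse_error_validation")
})

test_that("valence and activation composites follow the circumplex formulas", {
  expect_equal(
    affect_composites(tibble::tibble(pa = 5, pd = 5, na = 5, nd = 5))[
      , c("valence", "activation")],
    tibble::tibble(valence = 0, activation = 0)
  )
  expect_equal(
    affect_composites(tibble::tibble(pa = 9, pd = 9, na = 1, nd = 1))[
      , c("valence", "activation")],
    tibble::tibble(valence = 16, activation = 0)
  )
  expect_equal(
    affect_composites(tibble::tibble(pa = 9, pd = 1, na = 9, nd = 1))[
      , c("valence", "activation")],
    tibble::tibble(valence = 0, activation = 16)
  )
  # general case against direct arithmetic
  expect_equal(
    affect_composites(tibble::tibble(pa = 7, pd = 2, na = 4, nd = 6))$valence,
    (7 + 2) - (4 + 6)
  )
})

test_that("resultant length ratio matches direction geometry", {
  expect_identical(resultant_length_ratio(c(3, 3, 3), c(4, 4, 4)), 1)
  expect_equal(resultant_length_ratio(c(1, -1), c(0, 0)), 0)
  expect_equal(resultant_length_ratio(c(1, 0), c(0, 1)), sqrt(2) / 2,
               tolerance = 1e-12)
  # magnitudes are irrelevant: same directions, wildly different lengths
  expect_equal(resultant_length_ratio(c(0.1, 0), c(0, 50)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(resultant_length_ratio(3, 4),
               class = "spinpulse_error_insufficient_data")
  # degenerate origin points are dropped, then too few remain
  expect_error(resultant_length_ratio(c(0, 1), c(0, 0)),
               class = "spinpulse_error_insufficient_data")
})

test_that("spin boundary behavior and variants", {
  expect_identical(affect_spin(c(3, 3, 3), c(4, 4, 4)), 0)
  expect_identical(affect_spin(c(1, -1), c(0, 0)), Inf)
  expect_equal(affect_spin(c(1, 0), c(0, 1)), sqrt(-2 * log(sqrt(2) / 2)),
               tolerance = 1e-12)
  expect_equal(affect_spin(c(1, 0), c(0, 1), variant = "neg2log"),
               -2 * log(sqrt(2) / 2), tolerance = 1e-12)
  # spin = 0 iff ratio = 1
  expect_identical(affect_spin(c(2, 4, 6), c(2, 4, 6)), 0)
})

test_that("pulse is the SD of distances from the neutral origin", {
  expect_equal(affect_pulse(c(3, 0, -3), c(4, 5, -4)), 0)
  # distances {3, 4, 5} -> sample SD 1
  expect_equal(affect_pulse(c(3, 0, 5), c(0, 4, 0)), 1)
  expect_equal(affect_pulse(c(3, 0, 5), c(0, 4, 0), sd_type = "population"),
               sd(c(3, 4, 5)) * sqrt(2 / 3))
  # the origin contributes distance 0 (not dropped)
  expect_equal(affect_pulse(c(0, 3), c(0, 4)), sd(c(0, 5)))
  expect_error(affect_pulse(3, 4),
               class = "spinpulse_error_insufficient_data")
})

test_that("uni-dimensional variabilities are plain SDs, order-invariant", {
  v <- affect_variability(c(-2, 0, 2), c(1, 1, 1))
  expect_equal(v$valence_variability, 2)
  expect_equal(v$activation_variability, 0)
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10); p <- sample(10)
  expect_equal(affect_variability(a, b), affect_variability(a[p], b[p]))
  expect_equal(affect_pulse(a, b), affect_pulse(a[p], b[p]))
  expect_equal(affect_spin(a, b), affect_spin(a[p], b[p]))
})

test_that("vector-formula spin equals the angle-space oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    v <- rnorm(n, sd = 4)
    a <- rnorm(n, sd = 4)
    expect_equal(affect_spin(v, a), circular_sd_angle_oracle(v, a),
                 tolerance = 1e-10)
    expect_equal(resultant_length_ratio(v, a), ratio_angle_oracle(v, a),
                 tolerance = 1e-10)
  }
})

test_that("spin is rotation- and scale-invariant; pulse scales linearly", {
  set.seed(7)
  for (i in 1:10) {
    v <- rnorm(8, sd = 3); a <- rnorm(8, sd = 3)
    phi <- runif(1, -pi, pi)
    vr <- v * cos(phi) - a * sin(phi)
    ar <- v * sin(phi) + a * cos(phi)
    expect_equal(affect_spin(vr, ar), affect_spin(v, a), tolerance = 1e-10)
    expect_equal(resultant_length_ratio(vr, ar),
                 resultant_length_ratio(v, a), tolerance = 1e-10)
    k <- runif(1, 0.1, 10)
    expect_equal(affect_spin(k * v, k * a), affect_spin(v, a),
                 tolerance = 1e-10)
    expect_equal(affect_pulse(k * v, k * a), k * affect_pulse(v, a),
                 tolerance = 1e-10)
  }
})

test_that("ratio stays in [0, 1] and spin decreases in the ratio", {
  set.seed(99)
  for (i in 1:20) {
    v <- rnorm(12); a <- rnorm(12)
    r <- resultant_length_ratio(v, a)
    expect_gte(r, 0); expect_lte(r, 1)
  }
  rs <- seq(0.05, 0.999, length.out = 30)
  spins <- vapply(rs, spinpulse:::spin_from_ratio, numeric(1))
  expect_true(all(diff(spins) < 0))
})

test_that("per-person profiles bundle metrics with bookkeeping", {
  d <- tibble::tibble(
    participant_id = "p1", session_index = 1:14,
    valence = rep(3, 14), activation = rep(4, 14)
  )
  pr <- affect_profiles(d)
  expect_equal(pr$spin, 0)
  expect_equal(pr$pulse, 0)
  expect_equal(pr$valence_variability, 0)
  expect_equal(pr$activation_variability, 0)
  expect_equal(pr$resultant_length_ratio, 1)
  expect_equal(pr$mean_valence, 3)
  expect_equal(pr$n_sessions_used, 14)
  expect_equal(pr$n_degenerate_dropped, 0)

  # degenerate sessions are dropped from spin but kept in pulse
  d2 <- tibble::tibble(
    participant_id = "p2", session_index = 1:4,
    valence = c(0, 3, 3, 3), activation = c(0, 4, 4, 4)
  )
  pr2 <- affect_profiles(d2)
  expect_equal(pr2$n_degenerate_dropped, 1)
  expect_equal(pr2$spin, 0)
  expect_equal(pr2$pulse, sd(c(0, 5, 5, 5)))

  # profiles work from subscale columns and agree with the direct route
  d3 <- tibble::tibble(
    participant_id = "p3", session_index = 1:3,
    pa = c(7, 5, 6), pd = c(6, 4, 5), na = c(2, 3, 4), nd = c(1, 2, 3)
  )
  pr3 <- affect_profiles(d3)
  comp <- affect_composites(d3)
  expect_equal(pr3$spin, affect_spin(comp$valence, comp$activation))

  # profile values satisfy the type invariants on random input
  set.seed(5)
  d4 <- tidyr::expand_grid(participant_id = sprintf("q%02d", 1:8),
                           session_index = 1:6) |>
    dplyr::mutate(valence = rnorm(dplyr::n(), sd = 5),
                  activation = rnorm(dplyr::n(), sd = 5))
  pr4 <- affect_profiles(d4)
  expect_true(all(pr4$resultant_length_ratio >= 0 &
                    pr4$resultant_length_ratio <= 1))
  expect_true(all(pr4$spin >= 0))
  expect_true(all(pr4$pulse >= 0))
  expect_equal(nrow(pr4), 8)
})

test_that("realized spin tracks the generating angular SD across a grid", {
  set.seed(314)
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  mean_spin <- vapply(grid, function(s) {
    mean(replicate(200, {
      th <- rnorm(14, 0, s)
      affect_spin(cos(th), sin(th))
    }))
  }, numeric(1))
  expect_equal(cor(mean_spin, grid, method = "spearman"), 1)
})
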