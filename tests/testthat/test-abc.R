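test_that("prior draws follow the specification", {
  s1 <- sample_prior(200, seed = 1)
  s2 <- sample_prior(200, seed = 1)
  expect_identical(s1, s2)
  expect_true(all(s1$p_s_save >= 0 & s1$p_s_save <= 1))
  expect_true(all(s1$build_condition %in% 0:1))
  # flat scenario prior: each scenario near 1/4 at large n
  big <- sample_prior(100000, seed = 2)
  freq <- table(big$payoff_scenario) / nrow(big)
  sigma <- sqrt(0.25 * 0.75 / nrow(big))
  expect_true(all(abs(freq - 0.25) < 4 * sigma))
  expect_error(sample_prior(0), ">= 1")
  expect_error(prior_spec(p_s_save_shape = c(2, -1)), "positive")
  expect_error(prior_spec(scenario_probs = c(1, 1, 1, 1)), "summing to 1")
})

test_that("summary statistics reproduce the marginal fixture", {
  s <- summarize_households(ulaanbaatar_margins())
  expect_equal(unname(s),
               c(349, 264, 26, 186, 521, 304, 247, 578, 57, 81, 687))
  expect_equal(sum(s[1:4]), 825)
  expect_equal(sum(s[5:6]), 825)
  expect_equal(sum(s[7:8]), 825)
  expect_equal(sum(s[9:11]), 825)
  # a single household contributes exactly one count per block
  one <- tibble::tibble(
    household_id = 1L, time_in_env = 5L, savings = "has", tenure = "none",
    family = "couple", first_house = "mobile", current_house = "fixed",
    transition = transition_category("mobile", "fixed")
  )
  s1 <- summarize_households(one)
  expect_equal(sum(s1[1:4]), 1)
  expect_equal(sum(s1[5:6]), 1)
  expect_equal(unname(s1["trans_mobile_fixed"]), 1)
  expect_error(summarize_households(one[0, ]), "non-empty")
})

test_that("the distance is a symmetric non-negative sum of deviations", {
  a <- summarize_households(ulaanbaatar_margins())
  expect_equal(abc_distance(a, a), 0)
  b <- a
  b[1] <- a[1] + 10
  b[2] <- a[2] - 10
  expect_equal(abc_distance(a, b), 20)
  set.seed(3)
  for (i in 1:1000) {
    x <- stats::rpois(11, 50)
    y <- stats::rpois(11, 50)
    expect_gte(abc_distance(x, y), 0)
    expect_equal(abc_distance(x, y), abc_distance(y, x))
  }
  expect_error(abc_distance(a, a[1:5]), "same length")
  # proportion scale is insensitive to sample size
  expect_equal(abc_distance(2 * a, a, scale = "proportion"), 0)
})

test_that("importance weights normalize and invert the distance order", {
  expect_equal(abc_weights(rep(3, 7)), rep(1 / 7, 7))
  expect_equal(abc_weights(c(0, log(2))), c(2 / 3, 1 / 3))
  set.seed(4)
  d <- stats::rexp(1e6, rate = 1 / 50)
  w <- abc_weights(d)
  expect_lt(abs(sum(w) - 1), 1e-10)
  expect_true(all(w >= 0))
  expect_equal(order(w, decreasing = TRUE), order(d))
  expect_equal(which.max(w), which.min(d))
  expect_error(abc_weights(numeric()), "non-empty")
  expect_error(abc_weights(c(1, -2)), "non-negative")
})

small_abc <- function(n_draws = 60, seed = 5, ...) {
  p <- model_params(0.5, 0.75, 0.25, build_condition = 1L, horizon = 15L)
  times <- rep(c(4L, 9L, 15L), 20)
  ref <- generate_reference_dataset(p, times, seed = 100)
  run_abc(ref, times, n_draws = n_draws,
          prior = prior_spec(horizon = 15L), seed = seed, ...)
}

test_that("the ABC run is deterministic, weighted and well-formed", {
  a1 <- small_abc()
  a2 <- small_abc()
  expect_identical(a1$draws, a2$draws)
  expect_lt(abs(sum(a1$draws$weight) - 1), 1e-10)
  expect_equal(which.max(a1$draws$weight), which.min(a1$draws$distance))
  expect_equal(nrow(tidy(a1)), 60L)
  expect_equal(glance(a1)$n_households, 60L)
  # a single draw carries the whole weight
  one <- small_abc(n_draws = 1)
  expect_equal(one$draws$weight, 1)
})

test_that("checkpointed ABC runs resume to identical results", {
  path <- withr::local_tempfile(fileext = ".csv")
  full <- small_abc(n_draws = 40, checkpoint_every = 10L)
  part <- small_abc(n_draws = 40, checkpoint_every = 10L,
                    checkpoint_path = path)
  expect_identical(full$draws, part$draws)
  # truncate the checkpoint to two chunks and resume
  done <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(done[1:20, ], path)
  resumed <- small_abc(n_draws = 40, checkpoint_every = 10L,
                       checkpoint_path = path)
  expect_identical(full$draws, resumed$draws)
})

test_that("posterior resampling follows the weights", {
  a <- small_abc()
  # degenerate weights: every sample is the best draw
  a$draws$weight <- c(1, rep(0, nrow(a$draws) - 1))
  ps <- posterior_sample(a, m = 50, seed = 6)
  expect_true(all(ps$.draw == 1L))
  expect_equal(nrow(dplyr::distinct(ps)), 1L)
  # uniform weights: resampling frequencies within multinomial tolerance
  a$draws$weight <- rep(1 / nrow(a$draws), nrow(a$draws))
  m <- 60000L
  ps2 <- posterior_sample(a, m = m, seed = 7)
  counts <- table(factor(ps2$.draw, levels = seq_len(nrow(a$draws))))
  expected <- m / nrow(a$draws)
  sigma <- sqrt(m * (1 / 60) * (59 / 60))
  expect_true(all(abs(counts - expected) < 5 * sigma))
  expect_equal(nrow(posterior_sample(a, seed = 8)), 1000L)
})

test_that("the HPDI is the narrowest interval holding the requested mass", {
  expect_equal(unname(hpdi(rep(2, 10))), c(2, 2))
  set.seed(9)
  u <- runif(1e5)
  h <- hpdi(u)
  expect_lt(abs((h[["upper"]] - h[["lower"]]) - 0.89), 0.01)
  # a point mass plus an outlier: the interval hugs the mass
  h2 <- hpdi(c(rep(0.5, 98), 0, 1), mass = 0.89)
  expect_equal(unname(h2), c(0.5, 0.5))
  expect_error(hpdi(1), "at least 2")
})

test_that("posterior predictive simulations have the documented structure", {
  a <- small_abc()
  pb <- posterior_predictive(a, mode = "behaviour", n_samples = 4L,
                             n_agents = 30L, seed = 10)
  expect_equal(nrow(pb), 4L * 15L * 3L)
  totals <- dplyr::summarise(pb, n = sum(n), .by = c(sample, step))
  expect_true(all(totals$n == 30L))
  pt <- posterior_predictive(a, mode = "transitions", n_datasets = 5L,
                             seed = 11)
  expect_equal(nrow(pt), 5L * 4L)
  per_ds <- dplyr::summarise(pt, n = sum(n), .by = dataset)
  expect_true(all(per_ds$n == length(a$times)))
  expect_equal(length(attr(pt, "reference")), 4L)
  # degenerate posterior: all datasets share the generating parameters
  one <- small_abc(n_draws = 1)
  pt1 <- posterior_predictive(one, mode = "transitions", n_datasets = 3L,
                              seed = 12)
  expect_equal(nrow(pt1), 12L)
})

test_that("recovery validation reports medians, intervals and coverage", {
  truths <- tibble::tibble(
    p_s_save = 0.5, p_l_move = 0.25, p_h_build = 0.75,
    build_condition = 1L, payoff_scenario = "additive"
  )
  rep <- validate_recovery(truths, times = rep(c(5L, 10L, 15L), 15),
                           n_draws = 300, prior = prior_spec(horizon = 15L),
                           m_posterior = 200L, seed = 13)
  expect_equal(nrow(rep), 3L)
  expect_setequal(rep$parameter, c("p_s_save", "p_l_move", "p_h_build"))
  expect_true(all(rep$hpdi_lower <= rep$posterior_median))
  expect_true(all(rep$posterior_median <= rep$hpdi_upper))
  expect_type(rep$covered, "logical")
  expect_true(all(rep$min_distance <= rep$mean_distance))
})
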