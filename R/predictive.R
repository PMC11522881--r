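# Posterior predictive checks: re-run the generative model from posterior
# draws and compare with the reference data on the outcome scale.

params_from_draw <- function(draw, prior) {
  model_params(
    p_s_save = draw$p_s_save, p_h_build = draw$p_h_build,
    p_l_move = draw$p_l_move,
    p_s_loss = prior$p_s_loss, p_force_move = prior$p_force_move,
    build_condition = draw$build_condition,
    payoff_scenario = draw$payoff_scenario,
    horizon = prior$horizon,
    family_growth = prior$family_growth
  )
}

#' Posterior predictive simulations
#'
#' Two complementary checks on the outcome scale:
#'
#' * `mode = "behaviour"`: takes `n_samples` posterior draws and, for each,
#'   solves the dynamic program and simulates `n_agents` households over the
#'   full horizon, returning per-step behaviour-frequency curves (the
#'   posterior-implied optimal trajectory).
#' * `mode = "transitions"`: generates `n_datasets` datasets matched to the
#'   reference residence-time structure, assigning each household its own
#'   posterior draw, and returns the distribution of the four
#'   dwelling-transition frequencies across datasets.
#'
#' @param result A `dwell_abc` object.
#' @param mode `"behaviour"` or `"transitions"`.
#' @param times Residence times for `mode = "transitions"`; defaults to the
#'   reference times stored in `result`.
#' @param n_samples Posterior draws for `mode = "behaviour"` (default 100).
#' @param n_agents Agents per draw for `mode = "behaviour"` (default 1000).
#' @param n_datasets Generated datasets for `mode = "transitions"`
#'   (default 1000).
#' @param seed Optional integer seed.
#' @return For `"behaviour"`: a tibble (`sample`, `step`, `behaviour`, `n`).
#'   For `"transitions"`: a tibble (`dataset`, `transition`, `n`) with the
#'   reference transition counts attached as attribute `reference`.
#' @export
posterior_predictive <- function(result, mode = c("behaviour", "transitions"),
                                 times = NULL, n_samples = 100L,
                                 n_agents = 1000L, n_datasets = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(result, "dwell_abc"))
  mode <- rlang::arg_match(mode)
  if (!is.null(seed)) set.seed(seed)
  prior <- result$prior

  if (mode == "behaviour") {
    draws <- posterior_sample(result, m = n_samples)
    out <- purrr::map(seq_len(n_samples), function(i) {
      pol <- solve_policy_cached(draws[i, ], prior)
      traj <- simulate_agents(pol, n = n_agents, init = result$init)
      dplyr::mutate(behaviour_frequencies(traj), sample = i, .before = 1L)
    })
    return(dplyr::bind_rows(out))
  }

  times <- as.integer(times %||% result$times)
  a_init <- if (result$init == "all_mobile") 1L else 0L
  cache <- new.env(parent = emptyenv())
  out <- purrr::map(seq_len(n_datasets), function(ds) {
    draws <- posterior_sample(result, m = length(times))
    counts <- numeric(4)
    for (id in unique(draws$.draw)) {
      sel <- draws$.draw == id
      pol <- solve_policy_cached(draws[which(sel)[1], ], prior, cache)
      a <- cpp_args(pol$params)
      m <- cpp_cross_section(pol$policy, a$pss, a$phb, a$plm, a$psl, a$pfm,
                             a$bc, a$base, a$hb, a$tb, a$sp,
                             times[sel], a_init)
      tr <- m[, 2] * 2L + m[, 3] # first_house * 2 + current_house
      counts <- counts + tabulate(tr + 1L, nbins = 4L)
    }
    tibble::tibble(
      dataset = ds,
      transition = factor(dwell_transition_levels,
                          levels = dwell_transition_levels),
      n = counts
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "reference") <- result$ref_stats[1:4]
  out
}

# solve once per distinct parameter draw; keyed by the draw values
solve_policy_cached <- function(draw, prior, cache = NULL) {
  key <- paste(draw$p_s_save, draw$p_l_move, draw$p_h_build,
               draw$build_condition, draw$payoff_scenario, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  pol <- solve_strategy(params_from_draw(draw, prior))
  if (!is.null(cache)) cache[[key]] <- pol
  pol
}

#' Parameter-recovery validation
#'
#' Runs the whole inference loop on synthetic references generated at known
#' parameter values: for each truth, generate a reference dataset, run the
#' ABC, and report the posterior median, the 89% HPDI, whether it covers the
#' truth, the prior median for comparison, and the minimal/weighted-mean
#' predictive distances. The full-scale validation of the emulated study
#' used 20 truths, 1000 agents and 100,000 candidate draws; tests use
#' scaled-down sizes.
#'
#' @param truths A tibble with columns `p_s_save`, `p_l_move`, `p_h_build`,
#'   `build_condition`, `payoff_scenario` (one row per truth).
#' @param times Residence times used for both reference generation and the
#'   ABC simulations.
#' @param n_draws Candidate draws per truth.
#' @param prior A [prior_spec()].
#' @param m_posterior Posterior samples used for medians/HPDIs.
#' @param hpdi_mass HPDI mass (default 0.89).
#' @param scale,init Passed to [run_abc()].
#' @param seed Master integer seed.
#' @return A tibble with one row per (truth, continuous parameter):
#'   `truth_id`, `parameter`, `truth`, `posterior_median`, `hpdi_lower`,
#'   `hpdi_upper`, `covered`, `prior_median`, `beats_prior`, plus
#'   `min_distance` and `mean_distance` (weighted) per truth.
#' @export
validate_recovery <- function(truths, times, n_draws, prior = prior_spec(),
                              m_posterior = 1000L, hpdi_mass = 0.89,
                              scale = "count", init = "uniform", seed = NULL) {
  if (is.null(seed)) rlang::abort("`seed` is required")
  cont <- c("p_s_save", "p_l_move", "p_h_build")
  prior_med <- c(
    p_s_save = stats::qbeta(0.5, prior$p_s_save_shape[1], prior$p_s_save_shape[2]),
    p_l_move = stats::qbeta(0.5, prior$p_l_move_shape[1], prior$p_l_move_shape[2]),
    p_h_build = stats::qbeta(0.5, prior$p_h_build_shape[1], prior$p_h_build_shape[2])
  )
  out <- purrr::map(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    true_params <- params_from_draw(tr, prior)
    ref <- generate_reference_dataset(
      true_params, times,
      seed = (seed + 7L * i) %% .Machine$integer.max, init = init
    )
    abc <- run_abc(ref, times, n_draws = n_draws, prior = prior,
                   scale = scale, init = init,
                   seed = (seed + 7L * i + 3L) %% .Machine$integer.max)
    post <- posterior_sample(abc, m = m_posterior,
                             seed = (seed + 7L * i + 5L) %% .Machine$integer.max)
    w <- abc$draws$weight
    purrr::map(cont, function(par) {
      hi <- hpdi(post[[par]], mass = hpdi_mass)
      tibble::tibble(
        truth_id = i,
        parameter = par,
        truth = tr[[par]],
        posterior_median = median(post[[par]]),
        hpdi_lower = hi[["lower"]],
        hpdi_upper = hi[["upper"]],
        covered = tr[[par]] >= hi[["lower"]] && tr[[par]] <= hi[["upper"]],
        prior_median = prior_med[[par]],
        beats_prior = abs(median(post[[par]]) - tr[[par]]) <
          abs(prior_med[[par]] - tr[[par]]),
        min_distance = min(abc$draws$distance),
        mean_distance = sum(w * abc$draws$distance)
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}
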