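#' Initialize agents in the state space
#'
#' @param n Number of agents.
#' @param mode `"uniform"` draws independently and uniformly over the 24
#'   configurations; `"all_mobile"` fixes the house state at `mobile`
#'   (households typically arrive with a mobile dwelling) and draws the
#'   remaining states uniformly.
#' @param seed Optional integer seed.
#' @return A tibble of start states (one row per agent) with an `agent`
#'   column and the state columns of [state_space()].
#' @export
#' @examples
#' init_agents(3, seed = 1)
init_agents <- function(n, mode = c("uniform", "all_mobile"), seed = NULL) {
  mode <- rlang::arg_match(mode)
  if (n < 0) rlang::abort("`n` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ids <- if (mode == "uniform") {
    sample.int(24L, n, replace = TRUE) - 1L
  } else {
    sample.int(12L, n, replace = TRUE) - 1L # ids 0..11 are the mobile states
  }
  dplyr::bind_cols(tibble::tibble(agent = seq_len(n)), state_config(ids))
}

resolve_init <- function(init, n, seed_done) {
  if (is.character(init)) {
    if (is.null(n)) rlang::abort("`n` is required when `init` is a mode name")
    mode <- rlang::arg_match(init, c("uniform", "all_mobile"))
    ids <- if (mode == "uniform") {
      sample.int(24L, n, replace = TRUE) - 1L
    } else {
      sample.int(12L, n, replace = TRUE) - 1L
    }
    return(ids)
  }
  if (is.data.frame(init)) {
    ids <- if ("state_id" %in% names(init)) {
      vctrs_cast_state_id(init$state_id)
    } else {
      state_index(init$house, init$savings, init$tenure, init$family)
    }
  } else {
    ids <- vctrs_cast_state_id(init)
  }
  if (!is.null(n) && length(ids) != n) {
    rlang::abort("`init` supplies a different number of agents than `n`")
  }
  ids
}

#' Forward-simulate agents enacting an optimal strategy
#'
#' Each agent looks up the behaviour prescribed by the policy for its current
#' state and time step, enacts it by sampling the within-step event tree, and
#' logs the outcome, until its stay length is reached.
#'
#' @param policy A `dwell_policy` from [solve_strategy()]; the simulation
#'   uses the parameters the policy was solved under, so policy and dynamics
#'   cannot disagree.
#' @param n Number of agents (may be omitted when `init` supplies states).
#' @param stay_lengths Integer vector of per-agent stay lengths in
#'   `1..horizon`; a scalar is recycled. Default: the full horizon.
#' @param init Either an initialization mode (`"uniform"`, `"all_mobile"`),
#'   a vector of state ids, or a tibble of start states (e.g. from
#'   [init_agents()]).
#' @param seed Optional integer seed; identical seeds give identical
#'   trajectories.
#' @return A tibble with one row per agent-step: `agent`, `step`, the
#'   start-of-step state (`state_id` plus decoded columns), `behaviour`,
#'   `success` (NA when the behaviour was a no-op in that state),
#'   `savings_lost`, `forced_move`, `forced_tenure`, `family_event` and
#'   `next_state_id`. The horizon and parameters are carried as attributes.
#' @export
#' @examples
#' pol <- solve_strategy(model_params(0.5, 0.5, 0.5, horizon = 5))
#' simulate_agents(pol, n = 2, seed = 1)
simulate_agents <- function(policy, n = NULL, stay_lengths = NULL,
                            init = "uniform", seed = NULL) {
  stopifnot(inherits(policy, "dwell_policy"))
  params <- policy$params
  horizon <- ncol(policy$policy)
  if (!is.null(seed)) set.seed(seed)
  ids <- resolve_init(init, n, TRUE)
  n <- length(ids)
  stay <- if (is.null(stay_lengths)) rep(horizon, n) else {
    as.integer(rep_len(stay_lengths, n))
  }
  if (n > 0 && (any(stay < 1L) || any(stay > horizon))) {
    rlang::abort("stay lengths must lie in 1..horizon")
  }
  if (n == 0L) {
    m <- matrix(integer(), 0, 10)
  } else {
    a <- cpp_args(params)
    m <- cpp_simulate(policy$policy, a$pss, a$phb, a$plm, a$psl, a$pfm,
                      a$bc, a$base, a$hb, a$tb, a$sp,
                      as.integer(ids), stay)
  }
  cfg <- state_config(if (nrow(m)) m[, 3] else integer())
  out <- dplyr::bind_cols(
    tibble::tibble(agent = m[, 1], step = m[, 2]),
    cfg,
    tibble::tibble(
      behaviour = dwell_behaviours[m[, 4] + 1L],
      success = int_to_lgl(m[, 5]),
      savings_lost = int_to_lgl(m[, 6]),
      forced_move = int_to_lgl(m[, 7]),
      forced_tenure = int_to_lgl(m[, 8]),
      family_event = int_to_lgl(m[, 9]),
      next_state_id = m[, 10]
    )
  )
  attr(out, "horizon") <- horizon
  attr(out, "params") <- params
  out
}

int_to_lgl <- function(x) ifelse(is.na(x), NA, x == 1L)

#' Behaviour frequencies per time step
#'
#' Counts how many still-active agents enact each behaviour at each step; at
#' every step the three counts sum to the number of agents whose stay length
#' has not yet elapsed.
#'
#' @param trajectories Output of [simulate_agents()].
#' @return A tibble with columns `step`, `behaviour`, `n`, complete over all
#'   steps and behaviours (zero-filled).
#' @export
behaviour_frequencies <- function(trajectories) {
  horizon <- attr(trajectories, "horizon") %||%
    (if (nrow(trajectories)) max(trajectories$step) else 0L)
  if (horizon == 0L) {
    return(tibble::tibble(step = integer(), behaviour = character(), n = integer()))
  }
  trajectories |>
    dplyr::count(.data$step, .data$behaviour) |>
    tidyr::complete(
      step = seq_len(horizon),
      behaviour = dwell_behaviours,
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(.data$step, match(.data$behaviour, dwell_behaviours))
}

#' Dwelling-transition categories
#'
#' A household is categorized purely by its first and current dwelling type:
#' mobile-mobile, mobile-fixed, fixed-mobile or fixed-fixed (empirically:
#' ger-ger, ger-bashin, bashin-ger, bashin-bashin).
#'
#' @param first_house,current_house Character vectors with values `"mobile"`
#'   or `"fixed"`.
#' @return A factor with the four transition levels.
#' @export
#' @examples
#' transition_category("mobile", "fixed")
transition_category <- function(first_house, current_house) {
  ok <- first_house %in% dwell_house_levels & current_house %in% dwell_house_levels
  if (!all(ok)) rlang::abort("house states must be 'mobile' or 'fixed'")
  factor(
    paste(first_house, current_house, sep = "_"),
    levels = dwell_transition_levels
  )
}

#' Extract a cross-sectional household table from trajectories
#'
#' One record per agent, observed at the end of its stay: time in the
#' environment, end-of-stay savings/tenure/family, the first and current
#' dwelling type and the dwelling-transition category.
#'
#' @param trajectories Output of [simulate_agents()].
#' @return A tibble with columns `household_id`, `time_in_env`, `savings`,
#'   `tenure`, `family`, `first_house`, `current_house`, `transition`.
#' @export
cross_section <- function(trajectories) {
  if (!nrow(trajectories)) {
    return(tibble::tibble(
      household_id = integer(), time_in_env = integer(), savings = character(),
      tenure = character(), family = character(), first_house = character(),
      current_house = character(),
      transition = factor(character(), levels = dwell_transition_levels)
    ))
  }
  first <- trajectories |>
    dplyr::filter(.data$step == 1L) |>
    dplyr::select("agent", first_house = "house")
  last <- trajectories |>
    dplyr::group_by(.data$agent) |>
    dplyr::slice_max(.data$step, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  endcfg <- state_config(last$next_state_id)
  tibble::tibble(
    household_id = last$agent,
    time_in_env = last$step,
    savings = endcfg$savings,
    tenure = endcfg$tenure,
    family = endcfg$family,
    first_house = first$first_house[match(last$agent, first$agent)],
    current_house = endcfg$house
  ) |>
    dplyr::mutate(
      transition = transition_category(.data$first_house, .data$current_house)
    ) |>
    dplyr::arrange(.data$household_id)
}
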