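#' Family growth specification
#'
#' There is no behaviour that raises the family state directly; instead the
#' family advances one level per step with probability
#' `base_prob * (1 + house_bonus * h + tenure_bonus * l) * penalty`, where
#' `h`/`l` indicate a fixed house and tenure at the start of the step and
#' `penalty = savings_penalty` when savings are held (1 otherwise). The result
#' is clamped to \[0, 1\]. Covariates are read at the start of the step, so a
#' behaviour cannot influence family growth within its own step.
#'
#' @param base_prob Baseline per-step growth probability.
#' @param house_bonus,tenure_bonus Non-negative multiplier increments for a
#'   fixed house / held tenure.
#' @param savings_penalty Multiplier in \[0, 1\] applied while savings are
#'   held.
#' @return A list of class `dwell_growth`.
#' @export
#' @examples
#' family_growth_spec()
family_growth_spec <- function(base_prob = 0.1, house_bonus = 1,
                               tenure_bonus = 1, savings_penalty = 0.5) {
  stopifnot(
    is.numeric(base_prob), base_prob >= 0, base_prob <= 1,
    is.numeric(house_bonus), house_bonus >= 0,
    is.numeric(tenure_bonus), tenure_bonus >= 0,
    is.numeric(savings_penalty), savings_penalty >= 0, savings_penalty <= 1
  )
  structure(
    list(
      base_prob = base_prob, house_bonus = house_bonus,
      tenure_bonus = tenure_bonus, savings_penalty = savings_penalty
    ),
    class = "dwell_growth"
  )
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
  as.numeric(x)
}

#' Model parameters
#'
#' Bundles the five behaviour/shock probabilities, the build condition, the
#' terminal pay-off scenario and the decision horizon.
#'
#' @param p_s_save Probability that saving behaviour gains the savings state.
#' @param p_h_build Probability that building gains the house state
#'   (mobile to fixed). Under `build_condition = 1` building requires savings
#'   and consumes them on success.
#' @param p_l_move Probability that moving succeeds: tenure is gained and a
#'   fixed house is abandoned (house state reverts to mobile).
#' @param p_s_loss Per-step probability of losing held savings (shock).
#' @param p_force_move Per-step probability that an untenured household is
#'   forced to relocate: the house state reverts to mobile and tenure is
#'   gained with probability `p_l_move`.
#' @param build_condition 0 (savings not required to build) or 1 (required
#'   and consumed).
#' @param payoff_scenario One of [payoff_scenarios()].
#' @param horizon Number of decision steps (default 40, an adult lifespan).
#' @param family_growth A [family_growth_spec()].
#' @param payoff_weights Optional pay-off weight overrides, see
#'   [payoff_table()].
#' @return A list of class `dwell_params`.
#' @export
#' @examples
#' model_params(0.5, 0.5, 0.5, payoff_scenario = "additive")
model_params <- function(p_s_save, p_h_build, p_l_move,
                         p_s_loss = 0.1, p_force_move = 0.1,
                         build_condition = 0L,
                         payoff_scenario = "additive",
                         horizon = 40L,
                         family_growth = family_growth_spec(),
                         payoff_weights = NULL) {
  payoff_scenario <- rlang::arg_match(payoff_scenario, dwell_scenario_names)
  if (!build_condition %in% c(0L, 1L)) {
    rlang::abort("`build_condition` must be 0 or 1")
  }
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) rlang::abort("`horizon` must be >= 1")
  stopifnot(inherits(family_growth, "dwell_growth"))
  structure(
    list(
      p_s_save = check_prob(p_s_save, "p_s_save"),
      p_h_build = check_prob(p_h_build, "p_h_build"),
      p_l_move = check_prob(p_l_move, "p_l_move"),
      p_s_loss = check_prob(p_s_loss, "p_s_loss"),
      p_force_move = check_prob(p_force_move, "p_force_move"),
      build_condition = as.integer(build_condition),
      payoff_scenario = payoff_scenario,
      horizon = horizon,
      family_growth = family_growth,
      payoff_weights = payoff_weights
    ),
    class = "dwell_params"
  )
}

#' @export
print.dwell_params <- function(x, ...) {
  cat("<dwell_params>\n")
  cat(sprintf(
    "  p_s_save=%.3g  p_h_build=%.3g  p_l_move=%.3g  p_s_loss=%.3g  p_force_move=%.3g\n",
    x$p_s_save, x$p_h_build, x$p_l_move, x$p_s_loss, x$p_force_move
  ))
  cat(sprintf(
    "  build_condition=%d  scenario=%s  horizon=%d\n",
    x$build_condition, x$payoff_scenario, x$horizon
  ))
  invisible(x)
}

# unpack params into the argument order of the C++ routines
cpp_args <- function(params) {
  g <- params$family_growth
  list(
    pss = params$p_s_save, phb = params$p_h_build, plm = params$p_l_move,
    psl = params$p_s_loss, pfm = params$p_force_move,
    bc = params$build_condition,
    base = g$base_prob, hb = g$house_bonus, tb = g$tenure_bonus,
    sp = g$savings_penalty
  )
}
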