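#' Solve the housing decision program by backward induction
#'
#' Computes the optimal-behaviour tensor and the expected-terminal-pay-off
#' (value) tensor for a finite horizon. The boundary condition is
#' `V[s, horizon] = payoff(s)`; for earlier steps
#' `V[s, t] = max_b sum_s' K(s, b)(s') V[s', t+1]` and the policy records the
#' maximizing behaviour. Ties within `tie_tol` are broken in the fixed order
#' save > build > move (saving is prioritized).
#'
#' @param params A [model_params()] object.
#' @param tie_tol Absolute tolerance for declaring behaviours tied.
#' @return An object of class `dwell_policy` with elements `policy` (24 x
#'   horizon integer matrix of behaviour codes), `value` (24 x (horizon + 1)
#'   matrix), `params` and `tie_tol`. Use [tidy()] for a long table,
#'   [policy_array()] / [value_array()] for the state-shaped tensors.
#' @export
#' @examples
#' pol <- solve_strategy(model_params(0.5, 0.5, 0.5, horizon = 5))
#' tidy(pol)
solve_strategy <- function(params, tie_tol = 1e-12) {
  stopifnot(inherits(params, "dwell_params"))
  k <- kernel_array(params)
  payoff <- payoff_vector(params$payoff_scenario, params$payoff_weights)
  sol <- cpp_solve(k, payoff, params$horizon, tie_tol)
  structure(
    list(
      policy = sol$policy, value = sol$value,
      params = params, tie_tol = tie_tol
    ),
    class = "dwell_policy"
  )
}

#' @export
print.dwell_policy <- function(x, ...) {
  cat(sprintf(
    "<dwell_policy> %d states x %d steps, scenario=%s, build_condition=%d\n",
    nrow(x$policy), ncol(x$policy), x$params$payoff_scenario,
    x$params$build_condition
  ))
  tab <- table(factor(dwell_behaviours[x$policy + 1L], levels = dwell_behaviours))
  cat("  prescribed cells:",
      paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

state_dimnames <- function() {
  list(
    house = dwell_house_levels, savings = dwell_savings_levels,
    tenure = dwell_tenure_levels, family = dwell_family_levels
  )
}

#' Policy and value tensors in state-shaped form
#'
#' Reshape a solved policy into 5-dimensional arrays indexed by
#' (house, savings, tenure, family, time): 2 x 2 x 2 x 3 x horizon for the
#' policy and 2 x 2 x 2 x 3 x (horizon + 1) for the values (the extra slice
#' is the terminal pay-off).
#'
#' @param x A `dwell_policy` from [solve_strategy()].
#' @return A named array; policy cells hold behaviour labels.
#' @export
policy_array <- function(x) {
  stopifnot(inherits(x, "dwell_policy"))
  horizon <- ncol(x$policy)
  # canonical order is house-major with family fastest; aperm to state dims
  arr <- array(dwell_behaviours[t(x$policy) + 1L],
               dim = c(horizon, 3, 2, 2, 2))
  arr <- aperm(arr, c(5, 4, 3, 2, 1))
  dimnames(arr) <- c(state_dimnames(), list(time = seq_len(horizon)))
  arr
}

#' @rdname policy_array
#' @export
value_array <- function(x) {
  stopifnot(inherits(x, "dwell_policy"))
  nt <- ncol(x$value)
  arr <- array(t(x$value), dim = c(nt, 3, 2, 2, 2))
  arr <- aperm(arr, c(5, 4, 3, 2, 1))
  dimnames(arr) <- c(state_dimnames(), list(time = seq_len(nt)))
  arr
}

#' Tidy a solved policy into a long table
#'
#' One row per (state, decision step): the state configuration, the optimal
#' behaviour and the expected terminal pay-off when following the optimal
#' strategy from that step. The table round-trips through CSV.
#'
#' @param x A `dwell_policy`.
#' @param ... Unused.
#' @return A tibble with `24 * horizon` rows.
#' @export
tidy.dwell_policy <- function(x, ...) {
  horizon <- ncol(x$policy)
  out <- tidyr::expand_grid(state_id = 0:23, time = seq_len(horizon))
  cfg <- state_config(out$state_id)
  idx <- cbind(out$state_id + 1L, out$time)
  dplyr::bind_cols(
    cfg,
    tibble::tibble(
      time = out$time,
      behaviour = dwell_behaviours[x$policy[idx] + 1L],
      value = x$value[idx]
    )
  )
}

#' @rdname tidy.dwell_policy
#' @export
glance.dwell_policy <- function(x, ...) {
  tibble::tibble(
    horizon = ncol(x$policy),
    payoff_scenario = x$params$payoff_scenario,
    build_condition = x$params$build_condition,
    n_states = nrow(x$policy),
    mean_start_value = mean(x$value[, 1L])
  )
}
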