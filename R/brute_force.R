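# Exhaustive test oracle for the solver, kept deliberately independent of the
# compiled kernel: the one-step event tree is enumerated in R by walking every
# combination of event indicators, and values are computed by plain recursion
# over behaviours and outcomes with no memoization.

#' Enumerate one-step event outcomes (pure R)
#'
#' Walks every combination of the five within-step event indicators
#' (behaviour success, savings loss, forced move, tenure gain on forced move,
#' family growth), dropping combinations whose event cannot fire in the given
#' state, and aggregates the probability mass by end state. Used as the
#' independent reference for the compiled transition kernel and by
#' [brute_force_values()].
#'
#' @param state_id State id in 0--23.
#' @param behaviour One of [behaviours()].
#' @param params A [model_params()] object.
#' @return A tibble with columns `next_state_id` and `prob` (summing to 1).
#' @export
step_outcomes <- function(state_id, behaviour, params) {
  behaviour <- rlang::arg_match(behaviour, dwell_behaviours)
  d <- decode_state(vctrs_cast_state_id(state_id))
  h0 <- d$h; s0 <- d$s; l0 <- d$l; f0 <- d$f
  g <- params$family_growth
  grow <- min(1, max(0, g$base_prob * (1 + g$house_bonus * h0 + g$tenure_bonus * l0) *
                       (if (s0 == 1) g$savings_penalty else 1)))

  grid <- expand.grid(succ = 0:1, loss = 0:1, forced = 0:1, ften = 0:1, fam = 0:1)
  acc <- numeric(24)
  for (i in seq_len(nrow(grid))) {
    e <- grid[i, ]
    p <- 1
    h <- h0; s <- s0; l <- l0; f <- f0

    # behaviour resolution
    if (behaviour == "save") {
      if (s == 0) {
        p <- p * (if (e$succ == 1) params$p_s_save else 1 - params$p_s_save)
        if (e$succ == 1) s <- 1
      } else if (e$succ == 1) next # inapplicable indicator
    } else if (behaviour == "build") {
      can_build <- h == 0 && !(params$build_condition == 1 && s == 0)
      if (can_build) {
        p <- p * (if (e$succ == 1) params$p_h_build else 1 - params$p_h_build)
        if (e$succ == 1) {
          h <- 1
          if (params$build_condition == 1) s <- 0
        }
      } else if (e$succ == 1) next
    } else { # move
      p <- p * (if (e$succ == 1) params$p_l_move else 1 - params$p_l_move)
      if (e$succ == 1) { h <- 0; l <- 1 }
    }

    # savings-loss shock
    if (s == 1) {
      p <- p * (if (e$loss == 1) params$p_s_loss else 1 - params$p_s_loss)
      if (e$loss == 1) s <- 0
    } else if (e$loss == 1) next

    # forced-move shock (untenured only)
    if (l == 0) {
      p <- p * (if (e$forced == 1) params$p_force_move else 1 - params$p_force_move)
      if (e$forced == 1) {
        h <- 0
        p <- p * (if (e$ften == 1) params$p_l_move else 1 - params$p_l_move)
        if (e$ften == 1) l <- 1
      } else if (e$ften == 1) next
    } else if (e$forced == 1 || e$ften == 1) next

    # family growth (start-of-step covariates)
    p <- p * (if (e$fam == 1) grow else 1 - grow)
    if (e$fam == 1) f <- min(f + 1, 2)

    acc[encode_state(h, s, l, f) + 1L] <- acc[encode_state(h, s, l, f) + 1L] + p
  }
  tibble::tibble(next_state_id = which(acc > 0) - 1L, prob = acc[acc > 0])
}

#' Brute-force optimal values (test oracle)
#'
#' Computes the value tensor by exhaustive recursion over behaviours and
#' one-step event outcomes, with no memoization, entirely in R. Refused for
#' horizons above 4 (combinatorial blow-up). Intended as an independent
#' cross-check of [solve_strategy()].
#'
#' @param params A [model_params()] object; its `horizon` is capped by the
#'   `horizon` argument here.
#' @param horizon Horizon to evaluate, at most 4.
#' @return A 24 x (horizon + 1) matrix of values; column `t` holds the
#'   optimal expected terminal pay-off with `horizon - t + 1` steps to go.
#' @export
brute_force_values <- function(params, horizon = params$horizon) {
  stopifnot(inherits(params, "dwell_params"))
  horizon <- as.integer(horizon)
  if (horizon > 4L) {
    rlang::abort("brute_force_values is refused for horizon > 4")
  }
  payoff <- payoff_vector(params$payoff_scenario, params$payoff_weights)

  # one-step outcome tables (model definition, not value memoization)
  outcomes <- lapply(0:23, function(sid) {
    lapply(dwell_behaviours, function(b) step_outcomes(sid, b, params))
  })

  value_rec <- function(sid, steps_left) {
    if (steps_left == 0L) return(payoff[sid + 1L])
    best <- -Inf
    for (b in 1:3) {
      out <- outcomes[[sid + 1L]][[b]]
      ev <- 0
      for (r in seq_len(nrow(out))) {
        ev <- ev + out$prob[r] * value_rec(out$next_state_id[r], steps_left - 1L)
      }
      if (ev > best) best <- ev
    }
    best
  }

  vals <- matrix(NA_real_, 24, horizon + 1L)
  for (t in 0:horizon) {
    for (sid in 0:23) vals[sid + 1L, t + 1L] <- value_rec(sid, horizon - t)
  }
  vals
}
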