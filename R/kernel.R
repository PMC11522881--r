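# One-step transition law shared by the solver and the forward simulator.
# Within a step the events resolve in a fixed order:
#   1. behaviour (save / build / move), 2. savings-loss shock,
#   3. forced-move shock (only without tenure after step 2),
#   4. family growth (covariates read at the start of the step).

# 24 x 24 x 3 array (current state, next state, behaviour)
kernel_array <- function(params) {
  stopifnot(inherits(params, "dwell_params"))
  a <- cpp_args(params)
  k <- cpp_kernel(a$pss, a$phb, a$plm, a$psl, a$pfm, a$bc, a$base, a$hb, a$tb, a$sp)
  dimnames(k) <- list(NULL, NULL, dwell_behaviours)
  k
}

#' One-step transition distributions
#'
#' The exact distribution over next states when a household in a given state
#' enacts a behaviour, marginalizing over the within-step event tree
#' (behaviour outcome, savings-loss shock, forced-move shock, family growth).
#'
#' @param params A [model_params()] object.
#' @param state Optional state filter: integer state ids (0--23). Default all.
#' @param behaviour Optional behaviour filter, subset of [behaviours()].
#' @param keep_zero Keep zero-probability next states? Default drops them.
#' @return A tibble with columns `state_id`, `behaviour`, `next_state_id`,
#'   `prob`. For each (state, behaviour) pair the probabilities sum to 1.
#' @export
#' @examples
#' p <- model_params(0.5, 0.5, 0.5)
#' transition_kernel(p, state = 0, behaviour = "save")
transition_kernel <- function(params, state = NULL, behaviour = NULL,
                              keep_zero = FALSE) {
  k <- kernel_array(params)
  states <- if (is.null(state)) 0:23 else vctrs_cast_state_id(state)
  behs <- if (is.null(behaviour)) dwell_behaviours else {
    rlang::arg_match(behaviour, dwell_behaviours, multiple = TRUE)
  }
  out <- tidyr::expand_grid(
    state_id = states,
    behaviour = behs,
    next_state_id = 0:23
  )
  out$prob <- k[cbind(out$state_id + 1L, out$next_state_id + 1L,
                      match(out$behaviour, dwell_behaviours))]
  if (!keep_zero) out <- dplyr::filter(out, .data$prob > 0)
  out
}
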