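# State space: house (mobile/fixed) x savings (none/has) x tenure (none/has)
# x family (single/couple/family_with_dependants), 24 configurations.
# Canonical order is house-major: index = ((h*2 + s)*2 + l)*3 + f, so
# state_id 0 is (mobile, none, none, single). This matches the C++ core.

#' Behaviour and pay-off scenario labels
#'
#' The three behaviours a household can enact in each time step, and the four
#' terminal pay-off scenarios the model can optimize.
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' behaviours()
#' payoff_scenarios()
behaviours <- function() dwell_behaviours

#' @rdname behaviours
#' @export
payoff_scenarios <- function() dwell_scenario_names

# numeric level codes (0-based) for a state id vector
decode_state <- function(state_id) {
  list(
    h = state_id %/% 12L,
    s = (state_id %/% 6L) %% 2L,
    l = (state_id %/% 3L) %% 2L,
    f = state_id %% 3L
  )
}

encode_state <- function(h, s, l, f) ((h * 2L + s) * 2L + l) * 3L + f

#' Enumerate the household state space
#'
#' Returns all 24 state configurations in canonical (house-major) order,
#' together with their integer state ids. The id and the configuration are a
#' bijection: `state_index()` inverts the labels back to the id.
#'
#' @return A tibble with columns `state_id` (integer, 0--23), `house`
#'   (`"mobile"`/`"fixed"`), `savings` (`"none"`/`"has"`), `tenure`
#'   (`"none"`/`"has"`) and `family` (`"single"`, `"couple"`,
#'   `"family_with_dependants"`).
#' @export
#' @examples
#' state_space()
state_space <- function() {
  id <- 0:23
  d <- decode_state(id)
  tibble::tibble(
    state_id = id,
    house = dwell_house_levels[d$h + 1L],
    savings = dwell_savings_levels[d$s + 1L],
    tenure = dwell_tenure_levels[d$l + 1L],
    family = dwell_family_levels[d$f + 1L]
  )
}

#' Convert between state labels and state ids
#'
#' @param house,savings,tenure,family Character vectors of state levels (see
#'   [state_space()] for the admissible values). Recycled to a common length.
#' @param state_id Integer vector of state ids in 0--23.
#' @return `state_index()` returns an integer vector of ids; `state_config()`
#'   returns a tibble of decoded configurations.
#' @export
#' @examples
#' state_index("mobile", "none", "none", "single") # 0
#' state_config(23)
state_index <- function(house, savings, tenure, family) {
  h <- match(house, dwell_house_levels) - 1L
  s <- match(savings, dwell_savings_levels) - 1L
  l <- match(tenure, dwell_tenure_levels) - 1L
  f <- match(family, dwell_family_levels) - 1L
  if (anyNA(h) || anyNA(s) || anyNA(l) || anyNA(f)) {
    rlang::abort("unknown state level; see state_space() for admissible values")
  }
  encode_state(h, s, l, f)
}

#' @rdname state_index
#' @export
state_config <- function(state_id) {
  state_id <- vctrs_cast_state_id(state_id)
  d <- decode_state(state_id)
  tibble::tibble(
    state_id = state_id,
    house = dwell_house_levels[d$h + 1L],
    savings = dwell_savings_levels[d$s + 1L],
    tenure = dwell_tenure_levels[d$l + 1L],
    family = dwell_family_levels[d$f + 1L]
  )
}

vctrs_cast_state_id <- function(state_id) {
  state_id <- as.integer(state_id)
  if (anyNA(state_id) || any(state_id < 0L) || any(state_id > 23L)) {
    rlang::abort("state_id must be an integer in 0..23")
  }
  state_id
}

# default pay-off weight sets; every entry can be overridden via `weights`
default_payoff_weights <- function(scenario) {
  switch(scenario,
    material_baseline = list(savings = 0.5, tenure = 0.5),
    family_priority = list(family = c(0, 0.5, 1)),
    additive = list(house = 0.25, savings = 0.25, tenure = 0.25, family = 0.25),
    house_priority = list(house = 0.6, tenure = 0.25, savings = 0.15)
  )
}

#' Terminal pay-off tables
#'
#' Pay-offs accrued at the end of the decision horizon, per state
#' configuration, scaled to lie in \[0, 1\]. Four scenarios are built in:
#'
#' * `material_baseline`: only savings and tenure are rewarded,
#'   `w_s * s + w_l * l` (defaults 0.5/0.5). Serves as the logic check: no
#'   household should ever build under this scenario.
#' * `family_priority`: only the family state is rewarded (0, 0.5, 1 for the
#'   three levels).
#' * `additive`: every state matters equally,
#'   `(h + s + l + f/2) / 4` with the family level scaled to \[0, 1\].
#' * `house_priority`: family-insensitive; `0.6 h + 0.25 l + 0.15 s`, so the
#'   best configuration is house + tenure + savings and the second best is
#'   house + tenure, while a house alone pays less.
#'
#' @param scenario One of [payoff_scenarios()].
#' @param weights Optional named list overriding the scenario's default
#'   weights (`house`, `savings`, `tenure` scalars; `family` a length-3
#'   vector of level values).
#' @return A tibble of 24 rows: the state configuration plus a `payoff`
#'   column.
#' @export
#' @examples
#' payoff_table("house_priority")
payoff_table <- function(scenario, weights = NULL) {
  payoff <- payoff_vector(scenario, weights)
  dplyr::mutate(state_space(), payoff = payoff)
}

# 24-vector of terminal pay-offs in canonical state order
payoff_vector <- function(scenario, weights = NULL) {
  scenario <- rlang::arg_match(scenario, dwell_scenario_names)
  w <- default_payoff_weights(scenario)
  if (!is.null(weights)) {
    if (!is.list(weights) || is.null(names(weights))) {
      rlang::abort("`weights` must be a named list")
    }
    unknown <- setdiff(names(weights), names(w))
    if (length(unknown)) {
      rlang::abort(paste0(
        "unknown pay-off weight(s) for scenario '", scenario, "': ",
        paste(unknown, collapse = ", ")
      ))
    }
    w[names(weights)] <- weights
  }
  d <- decode_state(0:23)
  switch(scenario,
    material_baseline = w$savings * d$s + w$tenure * d$l,
    family_priority = w$family[d$f + 1L],
    additive = w$house * d$h + w$savings * d$s + w$tenure * d$l +
      w$family * (d$f / 2),
    house_priority = w$house * d$h + w$tenure * d$l + w$savings * d$s
  )
}
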