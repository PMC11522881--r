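# shared helpers: random parameter draws and small simulation fixtures

random_params <- function(horizon = 40L, scenario = NULL,
                          build_condition = NULL, growth = NULL) {
  model_params(
    p_s_save = runif(1), p_h_build = runif(1), p_l_move = runif(1),
    p_s_loss = runif(1), p_force_move = runif(1),
    build_condition = build_condition %||% sample(0:1, 1),
    payoff_scenario = scenario %||% sample(payoff_scenarios(), 1),
    horizon = horizon,
    family_growth = growth %||% family_growth_spec()
  )
}

frozen_params <- function(horizon = 10L, scenario = "additive") {
  model_params(
    0, 0, 0, 0, 0,
    payoff_scenario = scenario, horizon = horizon,
    family_growth = family_growth_spec(base_prob = 0)
  )
}

# terminal pay-off realized by each agent of a trajectory set
realized_payoffs <- function(trajectories, scenario) {
  xs <- cross_section(trajectories)
  ids <- state_index(xs$current_house, xs$savings, xs$tenure, xs$family)
  payoff_table(scenario)$payoff[ids + 1L]
}
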