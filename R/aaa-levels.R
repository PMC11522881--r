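# Canonical categorical levels, defined first (files load alphabetically).

dwell_house_levels <- c("mobile", "fixed")
dwell_savings_levels <- c("none", "has")
dwell_tenure_levels <- c("none", "has")
dwell_family_levels <- c("single", "couple", "family_with_dependants")
dwell_behaviours <- c("save", "build", "move")
dwell_scenario_names <- c(
  "material_baseline", "family_priority", "additive", "house_priority"
)
dwell_transition_levels <- c(
  "mobile_mobile", "mobile_fixed", "fixed_mobile", "fixed_fixed"
)

# order of the 11-component ABC summary vector
summary_stat_names <- c(
  paste0("trans_", dwell_transition_levels),
  "savings_none", "savings_has",
  "tenure_none", "tenure_has",
  paste0("family_", dwell_family_levels)
)
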