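# dwellsim

Households in rapidly growing settlements face a strategic problem: save,
build a fixed house, or move in search of secure land tenure? Each choice
pays off on a different time scale, is at the mercy of stochastic shocks
(losing savings, forced relocation), and feeds back on the others — a fixed
house is lost on relocation, savings may be required to build, and family
growth responds to housing, tenure and savings. `dwellsim` is for
researchers in human behavioural ecology and urban demography who want to
derive *optimal behavioural trajectories* for such households and to fit
the model's parameters to cross-sectional survey data by simulation-based
inference. Its empirical motivation is dwelling transitions (ger–bashin and
back) in the Ger districts of Ulaanbaatar, but every component is generic.

## The model in brief

A household is a point in a discrete state space
`house {mobile, fixed} x savings {0,1} x tenure {0,1} x family {single, couple, dependants}`
(24 configurations). Over a horizon of `T = 40` yearly steps it enacts one
behaviour per step (save / build / move), each succeeding with its own
probability (`p_s_save`, `p_h_build`, `p_l_move`), with per-step shocks
`p_s_loss` (savings loss) and `p_force_move` (forced relocation without
tenure). Terminal pay-offs `R(s)` over the 24 configurations define the
optimization goal (material baseline, family priority, additive, or house
priority). The solver computes

    V_T(s) = R(s),
    V_t(s) = max_b Σ_{s'} P(s' | s, b) V_{t+1}(s'),
    π_t(s) = argmax_b (ties: save ≻ build ≻ move)

by backward induction, yielding the optimal-strategy tensor
`π` of shape `2 x 2 x 2 x 3 x 40`. A forward simulator enacts `π` for agent
populations, producing longitudinal trajectories, behaviour-frequency
curves, and cross-sectional household records with dwelling-transition
categories.

The inference layer is approximate Bayesian computation with importance
weighting: candidate parameter draws (beta priors on the three behaviour
probabilities, Bernoulli on the build condition, flat over pay-off
scenarios) are pushed through solve-and-simulate, summarized into 11
frequencies (4 transition categories + savings 2 + tenure 2 + family 3),
scored by the summed absolute difference `d` to the reference summary, and
weighted by `w ∝ exp(−d)`. Posterior draws are resampled by weight; 89%
highest-posterior-density intervals summarize uncertainty; recovery
validation and posterior predictive checks close the loop.

## Worked example

```r
library(dwellsim)

# solve and inspect an optimal strategy
params <- model_params(0.5, 0.5, 0.5, 0.25, 0.25, payoff_scenario = "additive")
pol <- solve_strategy(params)
pol
#> <dwell_policy> 24 states x 40 steps, scenario=additive, build_condition=0
#>   prescribed cells: save=175  build=311  move=474

# simulate 100 households and summarize their behaviour
traj <- simulate_agents(pol, n = 100, seed = 1)
behaviour_frequencies(traj) |> dplyr::filter(step %in% c(1, 40))
#> # A tibble: 6 × 3
#>    step behaviour     n
#>   <int> <chr>     <int>
#> 1     1 save         29
#> 2     1 build        20
#> 3     1 move         51
#> 4    40 save        100
#> 5    40 build         0
#> 6    40 move          0

# fit the model to a synthetic reference by ABC
truth <- model_params(0.5, 0.75, 0.25, build_condition = 1, payoff_scenario = "additive")
times <- generate_time_structure(200, "uniform", seed = 2)
ref   <- generate_reference_dataset(truth, times, seed = 3)
abc   <- run_abc(ref, times, n_draws = 5000, seed = 11)
post  <- posterior_sample(abc, seed = 4)
round(c(median = median(post$p_s_save), hpdi(post$p_s_save)), 3)
#> median  lower  upper
#>  0.396  0.376  0.396
```

Early on most simulated households move (to secure tenure) or build; by
the final step every household saves — the additive pay-off rewards all
states, and savings are the last state worth topping up. In the ABC fit,
the posterior median of `p_s_save` moves from its prior median (0.264)
toward the generating value 0.5; at this desk scale the importance weights
concentrate on few draws, so the interval is narrow (see the vignette for
why, and for the full validation design).

`vignettes/housing-decision-model.Rmd` documents the model assumptions,
parameter defaults, numerical choices and the limitations of the
synthetic-data emulation.

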