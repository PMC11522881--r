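# ggplot2 helpers mirroring the standard diagnostic figures of this model
# family: behaviour-frequency curves, jittered dwelling-transition lines,
# and prior/posterior overlays.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot behaviour-frequency curves
#'
#' Lines of per-step counts of saving, building and moving agents. When the
#' input carries a `sample` (posterior predictive) or `rep`/`combo_id`
#' (sweep) column, one line per behaviour and group is drawn.
#'
#' @param freqs A tibble from [behaviour_frequencies()],
#'   [posterior_predictive()] (`mode = "behaviour"`), or the `frequencies`
#'   element of a [run_sweep()] result.
#' @return A ggplot object.
#' @export
plot_behaviour_frequencies <- function(freqs) {
  grp <- intersect(c("sample", "combo_id", "rep"), names(freqs))
  freqs <- dplyr::mutate(
    freqs,
    behaviour = factor(.data$behaviour, levels = dwell_behaviours),
    .line = if (length(grp)) {
      interaction(dplyr::pick(dplyr::all_of(c(grp, "behaviour"))))
    } else {
      .data$behaviour
    }
  )
  ggplot2::ggplot(freqs, ggplot2::aes(
    x = .data$step, y = .data$n,
    colour = .data$behaviour, group = .data$.line
  )) +
    ggplot2::geom_line(alpha = if (length(grp)) 0.4 else 1) +
    ggplot2::scale_colour_manual(
      values = c(save = "#2166ac", build = "#b2182b", move = "#762a83")
    ) +
    ggplot2::labs(x = "time step", y = "agents enacting behaviour",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot dwelling transitions over time
#'
#' One jittered line per agent showing its house state (mobile/fixed) across
#' its stay, coloured by the dwelling-transition category, in the style of
#' the standard transition plots for this model family.
#'
#' @param trajectories Output of [simulate_agents()].
#' @param jitter Vertical jitter half-width.
#' @return A ggplot object.
#' @export
plot_dwelling_transitions <- function(trajectories, jitter = 0.18) {
  xs <- cross_section(trajectories)
  d <- trajectories |>
    dplyr::transmute(
      agent = .data$agent, step = .data$step,
      house_num = as.integer(.data$house == "fixed")
    )
  # append the end-of-final-step house state so transitions are visible
  last <- trajectories |>
    dplyr::group_by(.data$agent) |>
    dplyr::slice_max(.data$step, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      agent = .data$agent, step = .data$step + 1L,
      house_num = state_config(.data$next_state_id)$house == "fixed"
    ) |>
    dplyr::mutate(house_num = as.integer(.data$house_num))
  d <- dplyr::bind_rows(d, last) |>
    dplyr::left_join(
      dplyr::select(xs, agent = "household_id", "transition"),
      by = "agent"
    )
  offs <- stats::runif(max(d$agent), -jitter, jitter)
  d$y <- d$house_num + offs[d$agent]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$step, y = .data$y, group = .data$agent,
    colour = .data$transition
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("mobile", "fixed")) +
    ggplot2::scale_colour_manual(values = c(
      mobile_mobile = "#8b0000", mobile_fixed = "#74add1",
      fixed_mobile = "#f46d43", fixed_fixed = "#00008b"
    ), drop = FALSE) +
    ggplot2::labs(x = "time in environment", y = "dwelling type",
                  colour = "transition") +
    ggplot2::theme_minimal()
}

#' Prior and posterior overlays
#'
#' Densities of the three behavioural probabilities in prior and posterior,
#' and bar charts for the pay-off scenario and build condition.
#'
#' @param result A `dwell_abc` object.
#' @param m Posterior (and prior) sample size for the overlay.
#' @param seed Optional integer seed.
#' @return A ggplot object (facetted).
#' @export
plot_posterior <- function(result, m = 1000L, seed = NULL) {
  stopifnot(inherits(result, "dwell_abc"))
  post <- posterior_sample(result, m = m, seed = seed)
  pri <- sample_prior(m, result$prior)
  both <- dplyr::bind_rows(
    dplyr::mutate(post[names(pri)], dist = "posterior"),
    dplyr::mutate(pri, dist = "prior")
  ) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("p_s_save", "p_l_move", "p_h_build")),
      names_to = "parameter", values_to = "value"
    )
  ggplot2::ggplot(both, ggplot2::aes(
    x = .data$value, colour = .data$dist, fill = .data$dist
  )) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dwell_abc <- function(object, ...) plot_posterior(object, ...)
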