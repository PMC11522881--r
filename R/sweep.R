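#' Theoretical parameter sweep grid
#'
#' The full-factorial sweep over the five behaviour/shock probabilities, the
#' build condition and the pay-off scenarios. With the defaults (three values
#' per probability, two build conditions, four scenarios) the grid has
#' `3^5 * 2 * 4 = 1944` combinations; each is intended to be run with 100
#' agents over 40 steps, 10 times.
#'
#' @param prob_values Values swept for each of the five probabilities.
#' @param build_conditions Build-condition values.
#' @param scenarios Pay-off scenarios to include.
#' @param n_agents,n_reps,horizon Run sizes, stored as attributes.
#' @return A tibble with one row per parameter combination (`combo_id` plus
#'   the parameter columns); attributes `n_agents`, `n_reps`, `horizon`.
#' @export
#' @examples
#' nrow(build_sweep_grid()) # 1944
build_sweep_grid <- function(prob_values = c(0.25, 0.5, 0.75),
                             build_conditions = c(0L, 1L),
                             scenarios = payoff_scenarios(),
                             n_agents = 100L, n_reps = 10L, horizon = 40L) {
  grid <- tidyr::expand_grid(
    p_s_save = prob_values,
    p_h_build = prob_values,
    p_l_move = prob_values,
    p_s_loss = prob_values,
    p_force_move = prob_values,
    build_condition = as.integer(build_conditions),
    payoff_scenario = scenarios
  )
  grid <- dplyr::mutate(grid, combo_id = dplyr::row_number(), .before = 1L)
  attr(grid, "n_agents") <- as.integer(n_agents)
  attr(grid, "n_reps") <- as.integer(n_reps)
  attr(grid, "horizon") <- as.integer(horizon)
  grid
}

grid_row_params <- function(row, horizon) {
  model_params(
    p_s_save = row$p_s_save, p_h_build = row$p_h_build,
    p_l_move = row$p_l_move, p_s_loss = row$p_s_loss,
    p_force_move = row$p_force_move,
    build_condition = row$build_condition,
    payoff_scenario = row$payoff_scenario,
    horizon = horizon
  )
}

#' Run a parameter sweep
#'
#' Solves and forward-simulates every grid combination `n_reps` times,
#' collecting per-step behaviour frequencies and end-of-stay
#' dwelling-transition records. Each (combination, replicate) is seeded
#' deterministically from the master seed, and with `out_dir` the results
#' are streamed to per-combination CSV files with a JSON manifest;
#' combinations whose files already exist are skipped (resumable) and read
#' back instead.
#'
#' @param grid A tibble from [build_sweep_grid()] (or a subset of its rows).
#' @param seed Master integer seed.
#' @param n_agents,n_reps,horizon Override the grid attributes.
#' @param init Initialization mode for agents (see [init_agents()]).
#' @param stay One of `"full"` (all agents stay the whole horizon) or
#'   `"varying"` (stay lengths drawn uniformly from `1..horizon`, as used for
#'   transition plots).
#' @param out_dir Optional directory for streamed CSV output.
#' @return An object of class `dwell_sweep`: a list with `frequencies`
#'   (tibble: combo_id, rep, step, behaviour, n), `transitions` (tibble of
#'   per-agent cross-section records with combo_id and rep) and `manifest`.
#' @export
run_sweep <- function(grid, seed, n_agents = NULL, n_reps = NULL,
                      horizon = NULL, init = "uniform",
                      stay = c("full", "varying"), out_dir = NULL) {
  stay <- rlang::arg_match(stay)
  n_agents <- n_agents %||% attr(grid, "n_agents") %||% 100L
  n_reps <- n_reps %||% attr(grid, "n_reps") %||% 10L
  horizon <- horizon %||% attr(grid, "horizon") %||% 40L
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  one_combo <- function(i) {
    row <- grid[i, ]
    freq_path <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("combo-%05d-frequencies.csv", row$combo_id))
    }
    trans_path <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("combo-%05d-transitions.csv", row$combo_id))
    }
    if (!is.null(out_dir) && file.exists(freq_path) && file.exists(trans_path)) {
      trans <- readr::read_csv(trans_path, show_col_types = FALSE)
      trans$transition <- factor(trans$transition,
                                 levels = dwell_transition_levels)
      return(list(
        freq = readr::read_csv(freq_path, show_col_types = FALSE),
        trans = trans
      ))
    }
    params <- grid_row_params(row, horizon)
    pol <- tryCatch(solve_strategy(params), error = function(e) {
      rlang::abort(sprintf("sweep combination %d failed: %s",
                           row$combo_id, conditionMessage(e)))
    })
    reps <- lapply(seq_len(n_reps), function(r) {
      set.seed((seed + 97L * row$combo_id + r) %% .Machine$integer.max)
      stay_lengths <- if (stay == "full") horizon else {
        sample.int(horizon, n_agents, replace = TRUE)
      }
      traj <- simulate_agents(pol, n = n_agents, stay_lengths = stay_lengths,
                              init = init)
      list(
        freq = dplyr::mutate(behaviour_frequencies(traj),
                             combo_id = row$combo_id, rep = r, .before = 1L),
        trans = dplyr::mutate(cross_section(traj),
                              combo_id = row$combo_id, rep = r, .before = 1L)
      )
    })
    freq <- dplyr::bind_rows(lapply(reps, `[[`, "freq"))
    trans <- dplyr::bind_rows(lapply(reps, `[[`, "trans"))
    if (!is.null(out_dir)) {
      readr::write_csv(freq, freq_path)
      readr::write_csv(trans, trans_path)
    }
    list(freq = freq, trans = trans)
  }

  res <- lapply(seq_len(nrow(grid)), one_combo)
  manifest <- list(
    seed = seed, n_agents = n_agents, n_reps = n_reps, horizon = horizon,
    init = init, stay = stay, n_combinations = nrow(grid),
    package_version = as.character(utils::packageVersion("dwellsim"))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(
    list(
      frequencies = dplyr::bind_rows(lapply(res, `[[`, "freq")),
      transitions = dplyr::bind_rows(lapply(res, `[[`, "trans")),
      manifest = manifest
    ),
    class = "dwell_sweep"
  )
}

#' @export
print.dwell_sweep <- function(x, ...) {
  cat(sprintf(
    "<dwell_sweep> %d combinations x %d replicates, %d agents, horizon %d\n",
    x$manifest$n_combinations, x$manifest$n_reps, x$manifest$n_agents,
    x$manifest$horizon
  ))
  invisible(x)
}
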