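# Run configuration (YAML) and manifests (JSON). Every analysis run can be
# reproduced from its manifest: the resolved configuration, the master seed
# and a hash of the configuration are recorded alongside the outputs.

run_config_keys <- list(
  params = c(
    "p_s_save", "p_h_build", "p_l_move", "p_s_loss", "p_force_move",
    "build_condition", "payoff_scenario", "horizon"
  ),
  family_growth = c("base_prob", "house_bonus", "tenure_bonus", "savings_penalty"),
  payoff_weights = c("house", "savings", "tenure", "family"),
  prior = c(
    "p_s_save_shape", "p_l_move_shape", "p_h_build_shape",
    "p_build_condition", "scenario_probs", "p_s_loss", "p_force_move", "horizon"
  ),
  simulation = c("n_agents", "n_reps", "stay", "init", "seed"),
  abc = c("n_draws", "scale", "m_posterior", "hpdi_mass", "checkpoint_every"),
  paths = c("input", "output")
)

#' Read and validate a run configuration
#'
#' YAML configuration with sections `params`, `family_growth`,
#' `payoff_weights`, `prior`, `simulation`, `abc` and `paths`; unknown
#' sections or keys are rejected so typos cannot silently change a run.
#'
#' @param path YAML file path.
#' @return A validated named list of class `dwell_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) rlang::abort("configuration must be a key-value mapping")
  unknown <- setdiff(names(cfg), names(run_config_keys))
  if (length(unknown)) {
    rlang::abort(paste0("unknown configuration section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), run_config_keys[[sec]])
    if (length(bad)) {
      rlang::abort(paste0("unknown key(s) in section '", sec, "': ",
                          paste(bad, collapse = ", ")))
    }
  }
  structure(cfg, class = "dwell_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(unclass(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Model parameters from a configuration
#'
#' @param cfg A `dwell_config` (or plain list with the same sections).
#' @return A [model_params()] object built from the `params`,
#'   `family_growth` and `payoff_weights` sections.
#' @export
config_params <- function(cfg) {
  p <- cfg$params %||% list()
  growth <- rlang::exec(family_growth_spec, !!!(cfg$family_growth %||% list()))
  rlang::exec(
    model_params,
    !!!p,
    family_growth = growth,
    payoff_weights = cfg$payoff_weights
  )
}

#' Write a reproducibility manifest
#'
#' JSON record of the resolved configuration, master seed, configuration
#' hash, package version and timestamp; an artifact is reproducible from its
#' manifest alone.
#'
#' @param path Output JSON path.
#' @param config Configuration list used for the run.
#' @param seed Master seed.
#' @param ... Further fields to record (sizes, output paths, ...).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, ...) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dwellsim")),
    seed = seed,
    config_hash = rlang::hash(config),
    config = config,
    ...
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
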