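# Pipeline plumbing: run configuration, deterministic sub-seed
# derivation, and the three stage drivers that tie the modules together.
# A thin command-line wrapper over these functions ships in
# inst/scripts/threshpgg-cli.R.

#' Derive a deterministic stage sub-seed from a global seed
#'
#' Folds the global seed and arbitrary stage labels (stage name,
#' treatment, ...) through a 31-multiplier string hash modulo `2^31 - 1`,
#' so each stochastic stage gets its own reproducible seed decoupled from
#' the others.
#'
#' @param seed Integer global seed.
#' @param ... Character labels identifying the stage.
#' @return A positive integer scalar below `2^31`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste(c(...), collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

.config_from_spec <- function(x) {
  if (inherits(x, "pgg_config")) return(x)
  if (is.character(x) && length(x) == 1) return(make_treatment(x))
  if (is.list(x)) {
    if (!is.null(x$treatment)) {
      return(make_treatment(x$treatment,
                            overrides = x[setdiff(names(x), "treatment")]))
    }
    return(do.call(game_config, x))
  }
  stop("cannot interpret game specification", call. = FALSE)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML/JSON file (or accepts a list) with optional blocks
#' `treatment`/`game` (a treatment label or explicit parameters),
#' `dynamics` ([dynamics_params()] arguments), `agent` ([agent_model()]
#' arguments), `out_dir`, `seed` and `log_level`.
#'
#' @param x Path to a YAML/JSON file, or a list.
#' @return A list of class `pgg_runconfig` with `config`, `dynamics`,
#'   `agent`, `out_dir`, `seed`.
#' @export
run_config <- function(x) {
  raw <- if (is.character(x) && length(x) == 1) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  } else x
  game_spec <- if (!is.null(raw$game)) raw$game else raw$treatment
  cfg <- if (is.null(game_spec)) make_treatment("full_equality") else
    .config_from_spec(game_spec)
  dyn <- if (is.null(raw$dynamics)) dynamics_params() else {
    if (!is.null(raw$dynamics$initial_mixture)) {
      raw$dynamics$initial_mixture <- unlist(raw$dynamics$initial_mixture)
    }
    do.call(dynamics_params, raw$dynamics)
  }
  agent <- if (is.null(raw$agent)) agent_model() else {
    if (!is.null(raw$agent$initial_mixture)) {
      raw$agent$initial_mixture <- unlist(raw$agent$initial_mixture)
    }
    do.call(agent_model, raw$agent)
  }
  structure(list(config = cfg, dynamics = dyn, agent = agent,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "pgg_runconfig")
}

.stage_log <- function(stage, seed, t0) {
  message(sprintf("[threshpgg] %s: seed=%d elapsed=%.2fs",
                  stage, seed, as.numeric(Sys.time()) - t0))
}

#' Equilibrium report stage
#'
#' Enumerates the pure Nash equilibria of one treatment, applies the five
#' selection heuristics and writes `equilibria_<name>.json`.
#'
#' @param treatment A treatment label, `pgg_config`, or game-spec list.
#' @param out_dir Output directory (created if needed).
#' @param overrides Named overrides when `treatment` is a label.
#' @return The report list, invisibly.
#' @export
pipeline_equilibria <- function(treatment, out_dir = ".", overrides = list()) {
  t0 <- as.numeric(Sys.time())
  cfg <- if (is.character(treatment) && length(overrides)) {
    make_treatment(treatment, overrides)
  } else .config_from_spec(treatment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0("equilibria_", cfg$name, ".json"))
  write_equilibrium_report(cfg, path)
  .stage_log("equilibria", 0L, t0)
  invisible(list(config = cfg,
                 equilibria = enumerate_pure_nash(cfg),
                 heuristics = heuristic_table(cfg),
                 path = path))
}

#' Dynamics stage
#'
#' Runs one dynamic from a chosen initial condition and writes the
#' trajectory CSV and a JSON summary (convergence, limit profile, modal
#' outcome).
#'
#' @param treatment Treatment label, `pgg_config` or game-spec list.
#' @param params A `pgg_dynparams`; its `dynamic` field selects the
#'   engine (for `"introspection"` the stationary distribution is
#'   computed instead of a trajectory).
#' @param init_kind `"uniform"`, `"random"` or `"empirical"`.
#' @param empirical_file CSV with columns `role`, `contribution`,
#'   `weight` (required when `init_kind = "empirical"` and
#'   `empirical_source` is NULL).
#' @param empirical_source Alternative in-memory source for the
#'   empirical initial condition.
#' @param out_dir Output directory.
#' @param seed Global seed; the stage sub-seed is derived from it.
#' @return Invisibly, the trajectory (or stationary distribution) plus
#'   output paths.
#' @export
pipeline_dynamics <- function(treatment, params = dynamics_params(),
                              init_kind = "uniform", empirical_file = NULL,
                              empirical_source = NULL, out_dir = ".",
                              seed = 1L) {
  t0 <- as.numeric(Sys.time())
  cfg <- .config_from_spec(treatment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub <- derive_seed(seed, "dynamics", params$dynamic, cfg$name)
  params$seed <- sub
  if (init_kind == "empirical" && is.null(empirical_source)) {
    if (is.null(empirical_file)) {
      stop("empirical initial condition requires empirical_file or ",
           "empirical_source", call. = FALSE)
    }
    empirical_source <- utils::read.csv(empirical_file)
  }
  init <- initial_condition(cfg, init_kind, source = empirical_source,
                            seed = derive_seed(seed, "init", cfg$name))
  stem <- file.path(out_dir, paste0("dynamics_", params$dynamic, "_", cfg$name))
  if (params$dynamic == "introspection") {
    stat <- introspection_stationary(cfg, params, mode = "exact")
    df <- data.frame(c1 = as.integer(rep(rownames(stat), ncol(stat))),
                     c2 = as.integer(rep(colnames(stat), each = nrow(stat))),
                     probability = as.vector(stat))
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
    top <- df[which.max(df$probability), ]
    jsonlite::write_json(list(treatment = cfg$name, dynamic = "introspection",
                              modal_profile = c(top$c1, top$c2)),
                         paste0(stem, "_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    .stage_log("dynamics", sub, t0)
    return(invisible(list(stationary = stat, path = paste0(stem, ".csv"))))
  }
  traj <- switch(params$dynamic,
    replicator = run_replicator(cfg, init, params),
    best_response = run_best_response(cfg, init, params),
    birth_death = run_birth_death(cfg, init, params))
  write_trajectory_csv(traj, paste0(stem, ".csv"))
  write_trajectory_summary(traj, paste0(stem, "_summary.json"))
  .stage_log("dynamics", sub, t0)
  invisible(list(trajectory = traj, path = paste0(stem, ".csv")))
}

#' Synthetic-experiment stage
#'
#' Simulates one synthetic cohort per requested treatment, writes the
#' session records CSV and a metrics JSON per treatment.
#'
#' @param treatments Character vector of treatment labels (or list of
#'   configs); defaults to all five.
#' @param n_pairs Pairs per cohort.
#' @param agent A `pgg_agent`.
#' @param rounds Rounds per game.
#' @param out_dir Output directory.
#' @param seed Global seed; per-treatment sub-seeds are derived.
#' @return Invisibly, a named list per treatment with `records` and
#'   `metrics`.
#' @export
pipeline_experiment <- function(treatments = TREATMENTS, n_pairs = 14,
                                agent = agent_model(), rounds = 20L,
                                out_dir = ".", seed = 1L) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (tr in treatments) {
    cfg <- .config_from_spec(tr)
    sub <- derive_seed(seed, "experiment", cfg$name)
    rec <- simulate_session(cfg, n_pairs = n_pairs, agent = agent,
                            seed = sub, rounds = rounds)
    write_records(rec, file.path(out_dir, paste0("records_", cfg$name, ".csv")))
    ms <- metrics_summary(rec, cfg)
    write_metrics_report(ms,
      json_path = file.path(out_dir, paste0("metrics_", cfg$name, ".json")),
      curves_path = file.path(out_dir, paste0("curves_", cfg$name, ".csv")))
    out[[cfg$name]] <- list(records = rec, metrics = ms)
  }
  .stage_log("experiment", seed, t0)
  invisible(out)
}
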