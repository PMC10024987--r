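#' Parameters for the evolutionary and learning dynamics
#'
#' @param dynamic One of `"replicator"`, `"best_response"`, `"birth_death"`,
#'   `"introspection"`.
#' @param selection_strength Fermi selection strength `beta` (birth-death
#'   and introspection).
#' @param mutation_rate Mutation probability `mu` in `[0, 1]` (birth-death).
#' @param population_size Subpopulation size `N` per role (birth-death,
#'   at least 2).
#' @param time_horizon Integration time (replicator) or number of steps
#'   (discrete dynamics).
#' @param step_size RK4 time step (replicator) or adjustment fraction
#'   (best-response).
#' @param seed Integer seed for stochastic dynamics.
#' @param convergence_tol Convergence tolerance on the per-step (per unit
#'   time for replicator) state change.
#' @return A list of class `pgg_dynparams`.
#' @export
dynamics_params <- function(dynamic = c("replicator", "best_response",
                                        "birth_death", "introspection"),
                            selection_strength = 1, mutation_rate = 0.01,
                            population_size = 100L, time_horizon = 2000,
                            step_size = 0.01, seed = NULL,
                            convergence_tol = 1e-8) {
  dynamic <- match.arg(dynamic)
  if (selection_strength < 0) stop("selection_strength must be >= 0", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  }
  if (dynamic == "birth_death" && population_size < 2) {
    stop("population_size must be >= 2 for birth_death", call. = FALSE)
  }
  structure(list(dynamic = dynamic, selection_strength = selection_strength,
                 mutation_rate = mutation_rate,
                 population_size = as.integer(population_size),
                 time_horizon = time_horizon, step_size = step_size,
                 seed = seed, convergence_tol = convergence_tol),
            class = "pgg_dynparams")
}

.as_state <- function(w, len, role) {
  w <- as.numeric(w)
  if (length(w) != len) {
    stop("role ", role, ": expected ", len, " weights (contributions 0..",
         len - 1, "), got ", length(w), call. = FALSE)
  }
  if (any(w < 0)) stop("role ", role, ": negative weights", call. = FALSE)
  s <- sum(w)
  if (s <= 0) stop("role ", role, ": weights sum to zero", call. = FALSE)
  w / s
}

#' Initial strategy distributions for the one-shot dynamics
#'
#' Builds the pair of per-role mixed strategies (weights over
#' contributions `0..e_i`) that a dynamic starts from.
#'
#' @param config A `pgg_config`.
#' @param kind `"uniform"` (all contributions equally likely), `"random"`
#'   (a symmetric Dirichlet(1) draw per role) or `"empirical"` (normalised
#'   copy of `source`).
#' @param source For `kind = "empirical"`: either a list with numeric
#'   vectors `x` (length `e1 + 1`) and `y` (length `e2 + 1`), or a data
#'   frame with columns `role`, `contribution`, `weight` (as produced by
#'   [first_round_distribution()] or read from file).
#' @param seed Seed for `kind = "random"`.
#' @return List with components `x` and `y`, each a probability vector.
#' @export
initial_condition <- function(config, kind = c("uniform", "random", "empirical"),
                              source = NULL, seed = NULL) {
  stopifnot(inherits(config, "pgg_config"))
  kind <- match.arg(kind)
  k1 <- config$e1 + 1L
  k2 <- config$e2 + 1L
  if (kind == "uniform") {
    return(list(x = rep(1 / k1, k1), y = rep(1 / k2, k2)))
  }
  if (kind == "random") {
    if (!is.null(seed)) set.seed(seed)
    rdir <- function(k) { g <- stats::rgamma(k, shape = 1); g / sum(g) }
    return(list(x = rdir(k1), y = rdir(k2)))
  }
  if (is.null(source)) stop("empirical initial condition requires a source", call. = FALSE)
  if (is.data.frame(source)) {
    need <- c("role", "contribution", "weight")
    if (!all(need %in% names(source))) {
      stop("empirical source needs columns role, contribution, weight", call. = FALSE)
    }
    vec <- function(role, k) {
      rows <- source[source$role == role, ]
      w <- rep(0, k)
      if (any(rows$contribution < 0 | rows$contribution > k - 1)) {
        stop("role ", role, ": contribution outside 0..", k - 1, call. = FALSE)
      }
      w[rows$contribution + 1] <- rows$weight
      w
    }
    source <- list(x = vec(1, k1), y = vec(2, k2))
  }
  list(x = .as_state(source$x, k1, 1), y = .as_state(source$y, k2, 2))
}

.new_trajectory <- function(config, params, eng) {
  final <- eng$states[[length(eng$states)]]
  limit <- if (isTRUE(eng$converged)) {
    c(which.max(final$x) - 1L, which.max(final$y) - 1L)
  } else NULL
  structure(list(times = eng$times, states = eng$states,
                 converged = eng$converged, limit_profile = limit,
                 config = config, params = params),
            class = "pgg_trajectory")
}

#' @export
print.pgg_trajectory <- function(x, ...) {
  final <- x$states[[length(x$states)]]
  cat("Trajectory <", x$params$dynamic, "> on <", x$config$name, ">\n", sep = "")
  cat("  ", length(x$times), " recorded states, final time ",
      x$times[length(x$times)], "\n", sep = "")
  cat("  converged: ", x$converged,
      if (!is.null(x$limit_profile))
        paste0("  limit profile (", x$limit_profile[1], ", ",
               x$limit_profile[2], ")"), "\n", sep = "")
  mo <- modal_outcome(x)
  cat("  modal outcome (", mo[1], ", ", mo[2], ")\n", sep = "")
  invisible(x)
}

#' Two-population replicator dynamics
#'
#' Integrates the standard two-population replicator equation over the
#' contribution simplexes of the two roles: a contribution level's share
#' grows at a rate equal to its expected payoff against the co-role's
#' current mixture minus the role's mean payoff. Fixed-step RK4 with
#' per-step renormalisation of drift below 1e-6 (larger drift aborts).
#'
#' @param config A `pgg_config`.
#' @param init State pair from [initial_condition()].
#' @param params A `pgg_dynparams`; `step_size` is the RK4 time step.
#' @return A `pgg_trajectory`; `limit_profile` is the modal pure profile
#'   of the final state when converged.
#' @examples
#' fe <- make_treatment("full_equality")
#' tr <- run_replicator(fe, initial_condition(fe, "uniform"),
#'                      dynamics_params("replicator"))
#' modal_outcome(tr)  # (0, 0): defection takes over from uniform start
#' @export
run_replicator <- function(config, init, params = dynamics_params("replicator")) {
  m <- payoff_matrices(config)
  x <- .as_state(init$x, config$e1 + 1L, 1)
  y <- .as_state(init$y, config$e2 + 1L, 2)
  eng <- .replicator_engine(m$A, m$B, x, y, dt = params$step_size,
                            time_horizon = params$time_horizon,
                            tol = params$convergence_tol)
  .new_trajectory(config, params, eng)
}

#' Best-response dynamics
#'
#' Each discrete step moves a `step_size` fraction of each role's mass
#' toward the uniform mixture over that role's current best responses to
#' the co-role state; ties are split equally.
#'
#' @inheritParams run_replicator
#' @export
run_best_response <- function(config, init,
                              params = dynamics_params("best_response")) {
  m <- payoff_matrices(config)
  x <- .as_state(init$x, config$e1 + 1L, 1)
  y <- .as_state(init$y, config$e2 + 1L, 2)
  eng <- .best_response_engine(m$A, m$B, x, y, step_size = params$step_size,
                               n_steps = ceiling(params$time_horizon),
                               tol = params$convergence_tol)
  .new_trajectory(config, params, eng)
}

#' Stochastic birth-death (pairwise-comparison) dynamics
#'
#' Simulates one finite subpopulation of size `N` per role. Per step a
#' role is chosen at random; a focal and a model individual of that role
#' are drawn; expected payoffs are computed against the co-role
#' subpopulation mixture; the focal imitates the model with the Fermi
#' probability `1 / (1 + exp(-beta * (pi_model - pi_focal)))`, or, with
#' probability `mu`, adopts a uniformly random contribution instead.
#' Initial counts are apportioned from `init` by largest remainder, so
#' point-mass states start monomorphic.
#'
#' @inheritParams run_replicator
#' @export
run_birth_death <- function(config, init,
                            params = dynamics_params("birth_death")) {
  if (is.null(params$seed)) stop("birth_death requires params$seed", call. = FALSE)
  if (params$population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  m <- payoff_matrices(config)
  x <- .as_state(init$x, config$e1 + 1L, 1)
  y <- .as_state(init$y, config$e2 + 1L, 2)
  set.seed(params$seed)
  eng <- .birth_death_engine(m$A, m$B,
                             .apportion(x, params$population_size),
                             .apportion(y, params$population_size),
                             beta = params$selection_strength,
                             mu = params$mutation_rate,
                             n_steps = ceiling(params$time_horizon))
  .new_trajectory(config, params, eng)
}

#' Stationary distribution of introspection dynamics
#'
#' Models a single pair of players. Each step one player is chosen
#' uniformly, a random alternative contribution is proposed uniformly
#' among the player's other contribution levels, and the player switches
#' with Fermi probability `1 / (1 + exp(-beta * (pi_new - pi_current)))`.
#' The induced Markov chain over joint contribution profiles is
#' irreducible and aperiodic for finite `beta`, so its stationary
#' distribution is unique; `mode = "exact"` solves it from the full
#' transition matrix, `mode = "simulated"` estimates it from one long
#' seeded run of `time_horizon` steps.
#'
#' @param config A `pgg_config`.
#' @param params A `pgg_dynparams` (uses `selection_strength`, `seed`,
#'   `time_horizon`).
#' @param mode `"exact"` or `"simulated"`.
#' @return Matrix of stationary probabilities with rows `c1 = 0..e1` and
#'   columns `c2 = 0..e2`, summing to 1.
#' @examples
#' fe <- make_treatment("full_equality")
#' p0 <- introspection_stationary(fe, dynamics_params("introspection",
#'                                selection_strength = 0))
#' max(abs(p0 - 1 / length(p0)))  # ~0: uniform at beta = 0
#' @export
introspection_stationary <- function(config,
                                     params = dynamics_params("introspection"),
                                     mode = c("exact", "simulated")) {
  mode <- match.arg(mode)
  m <- payoff_matrices(config)
  beta <- params$selection_strength
  if (mode == "exact") {
    P <- .introspection_matrix(m$A, m$B, beta)
    pi <- .stationary(P)
    out <- matrix(pi, nrow = config$e1 + 1L)
  } else {
    if (is.null(params$seed)) stop("simulated mode requires params$seed", call. = FALSE)
    set.seed(params$seed)
    out <- .introspection_sim(m$A, m$B, beta, n_steps = ceiling(params$time_horizon))
  }
  dimnames(out) <- list(c1 = 0:config$e1, c2 = 0:config$e2)
  out
}

#' Introspection transition matrix over joint profiles
#'
#' Exposed for diagnostics: rows sum to 1 exactly, state `k` indexes the
#' profile `(c1, c2)` column-major with `c1` varying fastest.
#'
#' @inheritParams introspection_stationary
#' @return A `(e1+1)(e2+1)` square stochastic matrix.
#' @export
introspection_transition_matrix <- function(config,
                                            params = dynamics_params("introspection")) {
  m <- payoff_matrices(config)
  .introspection_matrix(m$A, m$B, params$selection_strength)
}

#' Modal pure outcome of a trajectory
#'
#' The pure profile maximising the product of the two roles' final
#' weights; ties break toward the lexicographically smallest `(c1, c2)`.
#'
#' @param trajectory A `pgg_trajectory`.
#' @return Integer vector `c(c1, c2)`.
#' @export
modal_outcome <- function(trajectory) {
  stopifnot(inherits(trajectory, "pgg_trajectory"))
  if (length(trajectory$states) == 0) stop("empty trajectory", call. = FALSE)
  final <- trajectory$states[[length(trajectory$states)]]
  joint <- outer(final$x, final$y)
  hits <- which(joint >= max(joint) - 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  unname(c(hits[1, 1] - 1L, hits[1, 2] - 1L))
}

#' Export a trajectory as a tidy CSV
#'
#' One row per recorded (time, role, contribution) with its weight.
#'
#' @param trajectory A `pgg_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pgg_trajectory"))
  rows <- lapply(seq_along(trajectory$times), function(k) {
    st <- trajectory$states[[k]]
    rbind(
      data.frame(time = trajectory$times[k], role = 1L,
                 contribution = seq_along(st$x) - 1L, weight = st$x),
      data.frame(time = trajectory$times[k], role = 2L,
                 contribution = seq_along(st$y) - 1L, weight = st$y))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' JSON summary of a trajectory
#'
#' @param trajectory A `pgg_trajectory`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_trajectory_summary <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pgg_trajectory"))
  mo <- modal_outcome(trajectory)
  s <- list(treatment = trajectory$config$name,
            dynamic = trajectory$params$dynamic,
            converged = trajectory$converged,
            final_time = trajectory$times[length(trajectory$times)],
            limit_profile = trajectory$limit_profile,
            modal_outcome = as.integer(mo))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
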