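#' Deterministic reactive strategy for the repeated game
#'
#' A reactive strategy contributes `opening` in round 1 and thereafter
#' `response[co_prev + 1]`, a function only of the co-player's
#' previous-round contribution.
#'
#' @param opening Round-1 contribution.
#' @param response Integer vector of length `e_other + 1`: own
#'   contribution for each possible co-player previous contribution
#'   `0..e_other`.
#' @param label Optional label.
#' @return An object of class `pgg_reactive`.
#' @export
reactive_strategy <- function(opening, response, label = NULL) {
  structure(list(opening = as.integer(opening),
                 response = as.integer(response),
                 label = label),
            class = "pgg_reactive")
}

.validate_reactive <- function(s, config, role) {
  e_self <- if (role == 1) config$e1 else config$e2
  e_other <- if (role == 1) config$e2 else config$e1
  if (length(s$response) != e_other + 1 || anyNA(s$response)) {
    stop("role ", role, ": response map must cover co-player contributions 0..",
         e_other, call. = FALSE)
  }
  vals <- c(s$opening, s$response)
  if (anyNA(vals) || any(vals < 0) || any(vals > e_self)) {
    stop("role ", role, ": strategy values outside {0, ..., ", e_self, "}",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Play the repeated game between two reactive strategies
#'
#' Deterministic play: round 1 uses the openings, round t applies each
#' response map to the co-player's round t-1 contribution. Because the
#' joint contribution profile is a deterministic state, play enters a
#' cycle within `(e1+1)(e2+1) + 1` rounds; the cycle is detected and mean
#' payoffs are averaged over one full cycle. If `rounds` is reached
#' before the cycle closes, means are taken over all played rounds
#' instead (useful for mirroring a 20-round experiment).
#'
#' @param config A `pgg_config`.
#' @param s1,s2 `pgg_reactive` strategies for roles 1 and 2.
#' @param rounds Maximum number of rounds (default: play to cycle closure).
#' @return List of class `pgg_repeated` with `per_round_profiles` (matrix
#'   with columns `c1`, `c2`), `cycle_start`, `cycle_length` (NA when not
#'   closed within `rounds`), and `mean_payoffs`.
#' @examples
#' fe <- make_treatment("full_equality")
#' hold6 <- reactive_strategy(6, rep(6, 13))
#' play_repeated(fe, hold6, hold6)$mean_payoffs  # (16, 16) every round
#' @export
play_repeated <- function(config, s1, s2, rounds = NULL) {
  stopifnot(inherits(config, "pgg_config"))
  .validate_reactive(s1, config, 1)
  .validate_reactive(s2, config, 2)
  bound <- (config$e1 + 1L) * (config$e2 + 1L) + 1L
  n_play <- if (is.null(rounds)) bound else min(rounds, bound)
  if (!is.null(rounds) && rounds < 1) stop("rounds must be >= 1", call. = FALSE)
  prof <- matrix(NA_integer_, nrow = n_play, ncol = 2,
                 dimnames = list(NULL, c("c1", "c2")))
  seen <- new.env(hash = TRUE)
  cycle_start <- NA_integer_
  cycle_length <- NA_integer_
  c1 <- s1$opening; c2 <- s2$opening
  t_end <- n_play
  for (t in seq_len(n_play)) {
    prof[t, ] <- c(c1, c2)
    key <- paste0(c1, ",", c2)
    if (!is.null(seen[[key]])) {
      cycle_start <- seen[[key]]
      cycle_length <- t - cycle_start
      t_end <- t
      break
    }
    seen[[key]] <- t
    nxt1 <- s1$response[c2 + 1L]
    nxt2 <- s2$response[c1 + 1L]
    c1 <- nxt1; c2 <- nxt2
  }
  prof <- prof[seq_len(t_end), , drop = FALSE]
  avg_rows <- if (is.na(cycle_start)) seq_len(nrow(prof)) else
    seq.int(cycle_start, cycle_start + cycle_length - 1L)
  pays <- vapply(avg_rows, function(t) payoff(config, prof[t, 1], prof[t, 2]),
                 numeric(2))
  structure(list(per_round_profiles = prof,
                 cycle_start = cycle_start, cycle_length = cycle_length,
                 mean_payoffs = unname(rowMeans(pays))),
            class = "pgg_repeated")
}

#' Reactive-strategy families
#'
#' Finite families of deterministic reactive strategies for one role:
#' `constant_strategies` holds every constant strategy (one per
#' contribution level); `linear_strategies` builds responses
#' `clip(round(a + b * c_other))` over grids of openings, intercepts and
#' slopes; `sampled_strategies` draws `K` random strategies under a seed.
#'
#' @param config A `pgg_config`.
#' @param role 1 or 2.
#' @return List of `pgg_reactive` strategies.
#' @export
constant_strategies <- function(config, role) {
  e_self <- if (role == 1) config$e1 else config$e2
  e_other <- if (role == 1) config$e2 else config$e1
  lapply(0:e_self, function(c) {
    reactive_strategy(c, rep(c, e_other + 1), label = paste0("const", c))
  })
}

#' @rdname constant_strategies
#' @param openings,intercepts,slopes Grids for the linear family.
#' @export
linear_strategies <- function(config, role,
                              openings = NULL, intercepts = NULL,
                              slopes = c(-1, 0, 0.5, 1)) {
  e_self <- if (role == 1) config$e1 else config$e2
  e_other <- if (role == 1) config$e2 else config$e1
  if (is.null(openings)) openings <- c(0, floor(e_self / 2), e_self)
  if (is.null(intercepts)) intercepts <- c(0, floor(e_self / 2), e_self)
  grid <- expand.grid(o = openings, a = intercepts, b = slopes)
  out <- list()
  seen <- character()
  for (g in seq_len(nrow(grid))) {
    resp <- pmin(pmax(round(grid$a[g] + grid$b[g] * (0:e_other)), 0), e_self)
    key <- paste(c(grid$o[g], resp), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- reactive_strategy(
      grid$o[g], resp,
      label = sprintf("lin(o=%g,a=%g,b=%g)", grid$o[g], grid$a[g], grid$b[g]))
  }
  out
}

#' @rdname constant_strategies
#' @param K Number of random strategies.
#' @param seed Seed for the random draw.
#' @export
sampled_strategies <- function(config, role, K, seed) {
  e_self <- if (role == 1) config$e1 else config$e2
  e_other <- if (role == 1) config$e2 else config$e1
  set.seed(seed)
  lapply(seq_len(K), function(k) {
    reactive_strategy(sample(0:e_self, 1),
                      sample(0:e_self, e_other + 1, replace = TRUE),
                      label = paste0("sampled", k))
  })
}

.family_for_role <- function(config, role, family, family_params) {
  switch(family,
    constant = constant_strategies(config, role),
    linear = do.call(linear_strategies,
                     c(list(config = config, role = role),
                       family_params[intersect(names(family_params),
                                               c("openings", "intercepts", "slopes"))])),
    sampled = {
      if (is.null(family_params$K) || is.null(family_params$seed)) {
        stop("sampled family requires family_params$K and $seed", call. = FALSE)
      }
      sampled_strategies(config, role, family_params$K,
                         family_params$seed + role)
    },
    stop("unknown family '", family, "'", call. = FALSE))
}

#' Mean repeated-game payoff matrices over strategy families
#'
#' Entry `(i, j)` holds the cycle-average payoffs of family-1 strategy `i`
#' against family-2 strategy `j` under [play_repeated()].
#'
#' @param config A `pgg_config`.
#' @param fam1,fam2 Lists of `pgg_reactive` strategies for roles 1 and 2.
#' @param rounds Passed to [play_repeated()].
#' @return List with matrices `A` and `B`.
#' @export
repeated_payoff_matrices <- function(config, fam1, fam2, rounds = NULL) {
  if (length(fam1) == 0 || length(fam2) == 0) stop("empty strategy family", call. = FALSE)
  A <- matrix(0, length(fam1), length(fam2))
  B <- A
  for (i in seq_along(fam1)) {
    for (j in seq_along(fam2)) {
      mp <- play_repeated(config, fam1[[i]], fam2[[j]], rounds = rounds)$mean_payoffs
      A[i, j] <- mp[1]; B[i, j] <- mp[2]
    }
  }
  list(A = A, B = B)
}

#' Evolutionary selection over a reactive-strategy family
#'
#' Runs introspection or birth-death dynamics (the same engines as the
#' one-shot module) on the finite repeated game whose stage payoffs are
#' the cycle-average payoffs of [play_repeated()]. For the constant
#' family the payoff matrices equal the one-shot matrices, so the result
#' reduces exactly to the one-shot analysis.
#'
#' @param config A `pgg_config`.
#' @param family `"constant"`, `"linear"` or `"sampled"`.
#' @param family_params List: for `sampled`, `K` and `seed`; for `linear`,
#'   optional `openings`, `intercepts`, `slopes`.
#' @param params A `pgg_dynparams`; `dynamic` must be `"introspection"` or
#'   `"birth_death"`.
#' @param mode For introspection: `"exact"` (requires at most 1e4 joint
#'   states) or `"simulated"`.
#' @return List with `fam1`, `fam2`, and either `stationary` (matrix over
#'   strategy pairs, introspection) or `trajectory` (birth-death).
#' @export
evolve_reactive <- function(config, family = c("constant", "linear", "sampled"),
                            family_params = list(),
                            params = dynamics_params("introspection"),
                            mode = c("exact", "simulated")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  fam1 <- .family_for_role(config, 1, family, family_params)
  fam2 <- .family_for_role(config, 2, family, family_params)
  m <- repeated_payoff_matrices(config, fam1, fam2)
  if (params$dynamic == "birth_death") {
    if (is.null(params$seed)) stop("birth_death requires params$seed", call. = FALSE)
    set.seed(params$seed)
    n1 <- .apportion(rep(1 / length(fam1), length(fam1)), params$population_size)
    n2 <- .apportion(rep(1 / length(fam2), length(fam2)), params$population_size)
    eng <- .birth_death_engine(m$A, m$B, n1, n2,
                               beta = params$selection_strength,
                               mu = params$mutation_rate,
                               n_steps = ceiling(params$time_horizon))
    final <- eng$states[[length(eng$states)]]
    return(list(fam1 = fam1, fam2 = fam2, freq1 = final$x, freq2 = final$y,
                trajectory = eng))
  }
  if (params$dynamic != "introspection") {
    stop("evolve_reactive supports introspection or birth_death dynamics",
         call. = FALSE)
  }
  n_states <- length(fam1) * length(fam2)
  if (mode == "exact" && n_states > 1e4) {
    stop(n_states, " joint states exceed the exact-introspection limit; ",
         "use mode = 'simulated'", call. = FALSE)
  }
  stat <- if (mode == "exact") {
    matrix(.stationary(.introspection_matrix(m$A, m$B, params$selection_strength)),
           nrow = length(fam1))
  } else {
    if (is.null(params$seed)) stop("simulated mode requires params$seed", call. = FALSE)
    set.seed(params$seed)
    .introspection_sim(m$A, m$B, params$selection_strength,
                       n_steps = ceiling(params$time_horizon))
  }
  list(fam1 = fam1, fam2 = fam2, stationary = stat)
}

#' Scan a strategy family for the most profitable cycle
#'
#' Evaluates every strategy pair in the family and returns the repeated
#' outcome with maximal total mean payoff, together with the modal
#' per-round profile of its cycle. Ties break toward the smaller
#' contribution gap `|c1 - c2|`, then lexicographically.
#'
#' @inheritParams evolve_reactive
#' @return List with `outcome` (a `pgg_repeated`), `profile` (the modal
#'   cycle profile `c(c1, c2)`) and the winning pair's indices.
#' @examples
#' mp <- make_treatment("moderate_productivity")
#' best_cycle_payoff_scan(mp, "constant")$profile  # (6, 0), total payoff 30
#' @export
best_cycle_payoff_scan <- function(config, family = c("constant", "linear", "sampled"),
                                   family_params = list()) {
  family <- match.arg(family)
  fam1 <- .family_for_role(config, 1, family, family_params)
  fam2 <- .family_for_role(config, 2, family, family_params)
  best <- NULL
  for (i in seq_along(fam1)) {
    for (j in seq_along(fam2)) {
      out <- play_repeated(config, fam1[[i]], fam2[[j]])
      total <- sum(out$mean_payoffs)
      rows <- if (is.na(out$cycle_start)) seq_len(nrow(out$per_round_profiles)) else
        seq.int(out$cycle_start, out$cycle_start + out$cycle_length - 1L)
      cyc <- out$per_round_profiles[rows, , drop = FALSE]
      tab <- table(paste(cyc[, 1], cyc[, 2]))
      modal <- as.integer(strsplit(names(tab)[which.max(tab)], " ")[[1]])
      gap <- abs(modal[1] - modal[2])
      cand <- list(outcome = out, profile = modal, total = total, gap = gap,
                   i = i, j = j)
      if (is.null(best) ||
          total > best$total + 1e-9 ||
          (abs(total - best$total) <= 1e-9 &&
             (gap < best$gap ||
                (gap == best$gap &&
                   (modal[1] < best$profile[1] ||
                      (modal[1] == best$profile[1] && modal[2] < best$profile[2])))))) {
        best <- cand
      }
    }
  }
  best
}
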