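#' Directional-learning agent model for synthetic sessions
#'
#' A deliberately simple behavioural stand-in used to generate
#' experiment-shaped data. Agents open with one of four behaviours drawn
#' from `initial_mixture`: the half-endowment (equal relative
#' contributions) profile, the equal-absolute-contributions equilibrium
#' profile, zero, or a uniformly random contribution. In later rounds
#' they adjust directionally: after a failed round in which they gave
#' less than half their endowment they raise their contribution by `step`
#' with probability `adjust_up_prob`; after an over-threshold
#' (non-effective) success they lower it by `step` with probability
#' `adjust_down_prob`; with probability `noise_prob` any round's
#' contribution is replaced by a uniform random one.
#'
#' @param initial_mixture Named numeric weights over
#'   `c("erc", "eac", "zero", "random")`, summing to 1.
#' @param adjust_up_prob,adjust_down_prob Probabilities in `[0, 1]`.
#' @param step Positive integer adjustment size.
#' @param noise_prob Probability in `[0, 1]`.
#' @return A list of class `pgg_agent`.
#' @export
agent_model <- function(initial_mixture = c(erc = 0.6, eac = 0.2,
                                            zero = 0.1, random = 0.1),
                        adjust_up_prob = 0.5, adjust_down_prob = 0.3,
                        step = 1L, noise_prob = 0.05) {
  if (!setequal(names(initial_mixture), c("erc", "eac", "zero", "random"))) {
    stop("initial_mixture must have names erc, eac, zero, random", call. = FALSE)
  }
  if (any(initial_mixture < 0) || abs(sum(initial_mixture) - 1) > 1e-9) {
    stop("initial_mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  for (p in c(adjust_up_prob, adjust_down_prob, noise_prob)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (step < 1 || step != round(step)) stop("step must be a positive integer", call. = FALSE)
  structure(list(initial_mixture = initial_mixture[c("erc", "eac", "zero", "random")],
                 adjust_up_prob = adjust_up_prob,
                 adjust_down_prob = adjust_down_prob,
                 step = as.integer(step), noise_prob = noise_prob),
            class = "pgg_agent")
}

.opening_contribution <- function(type, config, role) {
  e_self <- if (role == 1) config$e1 else config$e2
  switch(type,
    erc = floor(e_self / 2),
    eac = {
      sel <- select_by_heuristic(config, "EAC", nearest = TRUE)
      if (is.null(sel)) floor(e_self / 2) else sel[[if (role == 1) "c1" else "c2"]]
    },
    zero = 0L,
    random = sample(0:e_self, 1))
}

.play_pair_rounds <- function(config, open1, open2, agent, n_rounds) {
  c1 <- open1; c2 <- open2
  out <- matrix(NA_real_, nrow = n_rounds, ncol = 7,
                dimnames = list(NULL, c("c1", "c2", "collective", "success",
                                        "effective", "pi1", "pi2")))
  half <- c(floor(config$e1 / 2), floor(config$e2 / 2))
  e <- c(config$e1, config$e2)
  for (t in seq_len(n_rounds)) {
    coll <- config$p1 * c1 + config$p2 * c2
    succ <- coll >= config$theta
    eff <- coll == config$theta
    pis <- payoff(config, c1, c2)
    out[t, ] <- c(c1, c2, coll, succ, eff, pis[1], pis[2])
    if (t == n_rounds) break
    cur <- c(c1, c2)
    for (role in 1:2) {
      if (stats::runif(1) < agent$noise_prob) {
        cur[role] <- sample(0:e[role], 1)
      } else if (!succ && out[t, role] < half[role] &&
                 stats::runif(1) < agent$adjust_up_prob) {
        cur[role] <- min(cur[role] + agent$step, e[role])
      } else if (succ && !eff && stats::runif(1) < agent$adjust_down_prob) {
        cur[role] <- max(cur[role] - agent$step, 0)
      }
    }
    c1 <- cur[1]; c2 <- cur[2]
  }
  out
}

.random_derangement <- function(n) {
  repeat {
    s <- sample.int(n)
    if (all(s != seq_len(n))) return(s)
  }
}

#' Simulate a synthetic experimental session
#'
#' Emulates the session structure of the behavioural experiment:
#' `2 * n_pairs` subjects are randomly paired with fixed roles and play
#' `rounds` rounds (game 1); they are then re-matched by a random
#' derangement of pairs with roles swapped and play another `rounds`
#' rounds with the new partner (game 2). All payoffs, success and
#' effectiveness flags are computed from the game definition. Identical
#' seeds give identical records.
#'
#' @param config A `pgg_config`.
#' @param n_pairs Number of pairs (at least 2; the role-swap re-match
#'   needs a second pair).
#' @param agent A `pgg_agent`.
#' @param seed Integer seed.
#' @param rounds Rounds per game (default 20).
#' @return A data frame of class `pgg_records` with columns `treatment`,
#'   `game`, `pair_id`, `round`, `role`, `subject_id`, `contribution`,
#'   `collective`, `success`, `effective`, `payoff`; two rows per
#'   pair-round; the config is kept in attribute `config`.
#' @examples
#' fe <- make_treatment("full_equality")
#' erc_only <- agent_model(c(erc = 1, eac = 0, zero = 0, random = 0),
#'                         noise_prob = 0)
#' rec <- simulate_session(fe, n_pairs = 4, erc_only, seed = 1)
#' mean(rec$success)  # 1: half-endowment play meets theta by construction
#' @export
simulate_session <- function(config, n_pairs, agent = agent_model(),
                             seed, rounds = 20L) {
  stopifnot(inherits(config, "pgg_config"), inherits(agent, "pgg_agent"))
  if (n_pairs < 2) {
    stop("n_pairs must be >= 2: game-2 re-matching with a new partner ",
         "is impossible with a single pair", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  n_sub <- 2L * n_pairs
  types <- sample(names(agent$initial_mixture), n_sub, replace = TRUE,
                  prob = agent$initial_mixture)
  perm <- sample.int(n_sub)
  g1_role1 <- perm[seq_len(n_pairs)]
  g1_role2 <- perm[n_pairs + seq_len(n_pairs)]
  sigma <- .random_derangement(n_pairs)
  games <- list(
    list(game = 1L, r1 = g1_role1, r2 = g1_role2),
    # game 2: former role-2 subjects take role 1, partnered (via the
    # derangement) with a former role-1 subject from a different pair
    list(game = 2L, r1 = g1_role2, r2 = g1_role1[sigma]))
  rows <- vector("list", 2L * n_pairs)
  k <- 0L
  for (g in games) {
    for (pr in seq_len(n_pairs)) {
      s1 <- g$r1[pr]; s2 <- g$r2[pr]
      open1 <- .opening_contribution(types[s1], config, 1)
      open2 <- .opening_contribution(types[s2], config, 2)
      m <- .play_pair_rounds(config, open1, open2, agent, rounds)
      k <- k + 1L
      rows[[k]] <- data.frame(
        treatment = config$name, game = g$game, pair_id = pr,
        round = rep(seq_len(rounds), each = 2),
        role = rep(1:2, times = rounds),
        subject_id = rep(c(s1, s2), times = rounds),
        contribution = as.integer(t(m[, c("c1", "c2")])),
        collective = rep(m[, "collective"], each = 2),
        success = rep(as.logical(m[, "success"]), each = 2),
        effective = rep(as.logical(m[, "effective"]), each = 2),
        payoff = as.numeric(t(m[, c("pi1", "pi2")])))
    }
  }
  rec <- do.call(rbind, rows)
  structure(rec, class = c("pgg_records", "data.frame"), config = config)
}

#' Per-role first-round contribution distributions
#'
#' The normalised histogram of round-1 contributions per role, used as
#' the empirical initial condition for the evolutionary dynamics.
#'
#' @param records A `pgg_records` data frame.
#' @param config Optional `pgg_config`; defaults to the records'
#'   `config` attribute.
#' @param pool_game2 Include game-2 first rounds (default: game 1 only).
#' @return List with probability vectors `x` (role 1, length `e1 + 1`)
#'   and `y` (role 2).
#' @export
first_round_distribution <- function(records, config = attr(records, "config"),
                                     pool_game2 = FALSE) {
  if (is.null(records) || nrow(records) == 0) stop("empty records", call. = FALSE)
  if (is.null(config)) stop("config required (records carry none)", call. = FALSE)
  r1 <- records[records$round == 1 & (pool_game2 | records$game == 1), ]
  if (nrow(r1) == 0) stop("records contain no round-1 rows", call. = FALSE)
  hist_role <- function(role, e) {
    cs <- r1$contribution[r1$role == role]
    tabulate(cs + 1L, nbins = e + 1L) / length(cs)
  }
  list(x = hist_role(1, config$e1), y = hist_role(2, config$e2))
}

#' Write and read session records as CSV
#'
#' The CSV round-trip is lossless. `read_records` validates the full
#' schema: two rows per pair-round, contributions within the role's
#' endowment, and `collective`, `success`, `effective` and `payoff`
#' consistent with recomputation from the game definition; the first
#' inconsistent row is named in the error.
#'
#' @param records A `pgg_records`.
#' @param path CSV path.
#' @return `write_records` the path, invisibly; `read_records` a
#'   validated `pgg_records`.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @param config A `pgg_config`; when `NULL`, rebuilt with
#'   [make_treatment()] from the treatment column (defaults only).
#' @export
read_records <- function(path, config = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(rec) == 0) stop("empty records file: ", path, call. = FALSE)
  need <- c("treatment", "game", "pair_id", "round", "role", "subject_id",
            "contribution", "collective", "success", "effective", "payoff")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("records schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(config)) {
    tr <- unique(rec$treatment)
    if (length(tr) != 1) stop("records mix treatments; pass config explicitly", call. = FALSE)
    config <- make_treatment(tr)
  }
  rec$success <- as.logical(rec$success)
  rec$effective <- as.logical(rec$effective)
  cnt <- table(paste(rec$game, rec$pair_id, rec$round))
  if (any(cnt != 2)) {
    bad <- names(cnt)[cnt != 2][1]
    stop("pair-round (game pair round = ", bad, ") does not have exactly two rows",
         call. = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    row <- rec[i, ]
    e <- if (row$role == 1) config$e1 else config$e2
    if (row$contribution < 0 || row$contribution > e) {
      stop("row ", i, ": contribution ", row$contribution,
           " outside role ", row$role, "'s range", call. = FALSE)
    }
  }
  key <- paste(rec$game, rec$pair_id, rec$round)
  for (k in unique(key)) {
    idx <- which(key == k)
    pair <- rec[idx, ]
    c1 <- pair$contribution[pair$role == 1]
    c2 <- pair$contribution[pair$role == 2]
    coll <- config$p1 * c1 + config$p2 * c2
    pis <- payoff(config, c1, c2)
    ok <- all(pair$collective == coll) &&
      all(pair$success == (coll >= config$theta)) &&
      all(pair$effective == (coll == config$theta)) &&
      isTRUE(all.equal(pair$payoff[pair$role == 1], pis[1])) &&
      isTRUE(all.equal(pair$payoff[pair$role == 2], pis[2]))
    if (!ok) {
      stop("rows ", paste(idx, collapse = ","),
           " (game pair round = ", k, "): stored outcome columns are ",
           "inconsistent with recomputed payoffs", call. = FALSE)
    }
  }
  structure(rec, class = c("pgg_records", "data.frame"), config = config)
}
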