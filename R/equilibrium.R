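#' Best responses to a fixed opponent contribution
#'
#' Exhaustively evaluates the focal player's payoff over `{0, ..., e_i}`
#' and returns all payoff-maximising own contributions.
#'
#' @param config A `pgg_config`.
#' @param role Focal player, 1 or 2.
#' @param opponent_contribution Integer contribution of the co-player.
#' @return Integer vector of maximising contributions.
#' @examples
#' fe <- make_treatment("full_equality")
#' best_responses(fe, 1, 6)  # 6: completing the threshold costs less than r
#' best_responses(fe, 1, 0)  # 0: reaching theta alone costs more than r
#' @export
best_responses <- function(config, role, opponent_contribution) {
  stopifnot(inherits(config, "pgg_config"))
  if (!role %in% 1:2) stop("role must be 1 or 2", call. = FALSE)
  if (role == 1) validate_profile(config, 0, opponent_contribution)
  else validate_profile(config, opponent_contribution, 0)
  ei <- if (role == 1) config$e1 else config$e2
  own <- 0:ei
  pays <- vapply(own, function(ci) {
    if (role == 1) payoff(config, ci, opponent_contribution)[1]
    else payoff(config, opponent_contribution, ci)[2]
  }, numeric(1))
  own[pays >= max(pays) - 1e-9]
}

#' Test a profile for pure Nash equilibrium
#'
#' A profile is an equilibrium when no player has a strictly
#' payoff-improving unilateral deviation; it is strict when every
#' deviation strictly lowers the deviator's payoff and weak when some
#' deviation ties.
#'
#' @inheritParams validate_profile
#' @return List with `is_equilibrium` (logical) and `strictness`
#'   (`"strict"`, `"weak"`, or `"none"`).
#' @export
is_nash <- function(config, c1, c2) {
  validate_profile(config, c1, c2)
  base <- payoff(config, c1, c2)
  strict <- TRUE
  for (role in 1:2) {
    ei <- if (role == 1) config$e1 else config$e2
    ci <- if (role == 1) c1 else c2
    for (dev in setdiff(0:ei, ci)) {
      alt <- if (role == 1) payoff(config, dev, c2)[1] else payoff(config, c1, dev)[2]
      if (alt > base[role] + 1e-9) {
        return(list(is_equilibrium = FALSE, strictness = "none"))
      }
      if (alt >= base[role] - 1e-9) strict <- FALSE
    }
  }
  list(is_equilibrium = TRUE, strictness = if (strict) "strict" else "weak")
}

#' Enumerate all pure Nash equilibria
#'
#' Scans all `(e1 + 1) * (e2 + 1)` pure profiles against the payoff
#' matrices. Equilibria are classified as `cooperative` when the
#' collective contribution reaches the threshold and `defective`
#' otherwise; any below-threshold equilibrium is necessarily `(0, 0)`,
#' since a contributing player would gain by withdrawing.
#'
#' @param config A `pgg_config`.
#' @return A data frame of class `pgg_equilibria` with columns `c1`, `c2`,
#'   `class`, `strictness`, `pi1`, `pi2` and the config in attribute
#'   `config`.
#' @examples
#' eq <- enumerate_pure_nash(make_treatment("moderate_productivity"))
#' subset(eq, class == "cooperative")  # all satisfy 2*c1 + c2 = 12
#' @export
enumerate_pure_nash <- function(config) {
  stopifnot(inherits(config, "pgg_config"))
  m <- payoff_matrices(config)
  colmax <- apply(m$A, 2, max)
  rowmax <- apply(m$B, 1, max)
  out <- list()
  for (j in seq_len(ncol(m$A))) {
    for (i in seq_len(nrow(m$A))) {
      if (m$A[i, j] >= colmax[j] - 1e-9 && m$B[i, j] >= rowmax[i] - 1e-9) {
        strict <- sum(m$A[, j] >= colmax[j] - 1e-9) == 1 &&
          sum(m$B[i, ] >= rowmax[i] - 1e-9) == 1
        c1 <- i - 1L; c2 <- j - 1L
        coop <- config$p1 * c1 + config$p2 * c2 >= config$theta
        out[[length(out) + 1]] <- data.frame(
          c1 = c1, c2 = c2,
          class = if (coop) "cooperative" else "defective",
          strictness = if (strict) "strict" else "weak",
          pi1 = m$A[i, j], pi2 = m$B[i, j])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(c1 = integer(), c2 = integer(), class = character(),
               strictness = character(), pi1 = numeric(), pi2 = numeric())
  res <- res[order(res$c1, res$c2), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pgg_equilibria", "data.frame"), config = config)
}

.cooperative_set <- function(config) {
  eq <- enumerate_pure_nash(config)
  eq[eq$class == "cooperative", , drop = FALSE]
}

#' Equilibrium-selection heuristics
#'
#' Selects one cooperative equilibrium of the one-shot game by a focal
#' principle:
#' \describe{
#'   \item{EAC}{equal absolute contributions, `c1 == c2`;}
#'   \item{ERC}{equal relative contributions, `c1/e1 == c2/e2`;}
#'   \item{ECC}{equal collective (effective) contributions, `p1*c1 == p2*c2`;}
#'   \item{EP}{equal payoffs, `pi1 == pi2`, with fallback to the
#'     cooperative equilibrium minimising `|pi1 - pi2|` when no exact
#'     solution exists;}
#'   \item{MCP}{maximal collective payoff `pi1 + pi2`, ties broken toward
#'     the smaller contribution gap `|c1 - c2|`, then lexicographically.}
#' }
#' EAC, ERC and ECC have no fallback: when their exact condition has no
#' integer solution inside the cooperative equilibrium set, `NULL` is
#' returned (or, with `nearest = TRUE`, the cooperative equilibrium
#' minimising the condition's absolute residual).
#'
#' @param config A `pgg_config`.
#' @param heuristic One of `"EAC"`, `"ERC"`, `"ECC"`, `"EP"`, `"MCP"`.
#' @param nearest Apply the nearest-residual fallback for EAC/ERC/ECC.
#' @return A one-row data frame (`c1`, `c2`, `pi1`, `pi2`) or `NULL`.
#' @examples
#' select_by_heuristic(make_treatment("moderate_endowment"), "ERC")  # (8, 4)
#' select_by_heuristic(make_treatment("strong_endowment"), "EAC")   # (6, 6)
#' @export
select_by_heuristic <- function(config, heuristic, nearest = FALSE) {
  heuristic <- match.arg(heuristic, c("EAC", "ERC", "ECC", "EP", "MCP"))
  coop <- .cooperative_set(config)
  if (nrow(coop) == 0) return(NULL)
  resid <- switch(heuristic,
    EAC = abs(coop$c1 - coop$c2),
    ERC = abs(coop$c1 / config$e1 - coop$c2 / config$e2),
    ECC = abs(config$p1 * coop$c1 - config$p2 * coop$c2),
    EP  = abs(coop$pi1 - coop$pi2),
    MCP = NULL)
  pick <- function(rows) rows[1, c("c1", "c2", "pi1", "pi2"), drop = FALSE]
  if (heuristic == "MCP") {
    total <- coop$pi1 + coop$pi2
    cand <- coop[total >= max(total) - 1e-9, , drop = FALSE]
    gap <- abs(cand$c1 - cand$c2)
    cand <- cand[gap <= min(gap) + 1e-9, , drop = FALSE]
    cand <- cand[order(cand$c1, cand$c2), , drop = FALSE]
    return(pick(cand))
  }
  exact <- coop[resid < 1e-9, , drop = FALSE]
  if (nrow(exact) > 0) return(pick(exact[order(exact$c1, exact$c2), , drop = FALSE]))
  if (heuristic == "EP" || nearest) {
    cand <- coop[resid <= min(resid) + 1e-9, , drop = FALSE]
    return(pick(cand[order(cand$c1, cand$c2), , drop = FALSE]))
  }
  NULL
}

#' Heuristic selection table for a configuration
#'
#' @param config A `pgg_config`.
#' @param nearest Passed to [select_by_heuristic()].
#' @return Data frame with one row per heuristic; `c1`/`c2` are `NA` when
#'   the heuristic selects nothing.
#' @export
heuristic_table <- function(config, nearest = FALSE) {
  hs <- c("EAC", "ERC", "ECC", "EP", "MCP")
  rows <- lapply(hs, function(h) {
    sel <- select_by_heuristic(config, h, nearest = nearest)
    if (is.null(sel)) {
      data.frame(heuristic = h, c1 = NA_integer_, c2 = NA_integer_,
                 pi1 = NA_real_, pi2 = NA_real_)
    } else {
      cbind(data.frame(heuristic = h), sel)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an equilibrium analysis as JSON
#'
#' Writes the equilibrium set and the heuristic table of a configuration.
#'
#' @param config A `pgg_config`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_equilibrium_report <- function(config, path) {
  eq <- enumerate_pure_nash(config)
  rep <- list(
    config = config[c("name", "e1", "e2", "p1", "p2", "r1", "r2", "theta")],
    equilibria = as.data.frame(eq),
    heuristics = heuristic_table(config))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
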