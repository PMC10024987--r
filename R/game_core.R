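#' Construct a threshold public goods game configuration
#'
#' A two-player threshold public goods game is parameterised by integer
#' endowments `e1`, `e2`, productivity factors `p1`, `p2`, rewards `r1`,
#' `r2` and a threshold `theta`. Each player `i` contributes an integer
#' `c_i` from `{0, ..., e_i}`; if the collective contribution
#' `p1*c1 + p2*c2` reaches `theta`, both players earn their reward on top
#' of what they kept.
#'
#' When `theta` is omitted it is derived from the half-endowment rule
#' `theta = (p1*e1 + p2*e2) / 2`, so that both players contributing half
#' their endowment meets the threshold exactly. Configurations with odd
#' endowments are accepted but carry `half_integer = FALSE`, since the
#' half-endowment profile is then not an integer contribution profile.
#'
#' @param e1,e2 Positive integer endowments (coins).
#' @param p1,p2 Positive integer productivity factors.
#' @param r1,r2 Positive rewards (coins); `r2` defaults to `r1`.
#' @param theta Positive threshold in effective-contribution units;
#'   derived from the half-endowment rule when `NULL`.
#' @param name Free-text label for the configuration.
#' @return An object of class `pgg_config`: a list with fields `e1`, `e2`,
#'   `p1`, `p2`, `r1`, `r2`, `theta`, `name` and `half_integer`.
#' @examples
#' cfg <- game_config(e1 = 12, e2 = 12, p1 = 1, p2 = 1, r1 = 10)
#' cfg$theta  # 12, from the half-endowment rule
#' @export
game_config <- function(e1, e2, p1 = 1, p2 = 1, r1 = 10, r2 = r1,
                        theta = NULL, name = "custom") {
  chk_posint <- function(x, what) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      stop(what, " must be a positive integer, got ", deparse(x), call. = FALSE)
    }
  }
  chk_posint(e1, "e1"); chk_posint(e2, "e2")
  chk_posint(p1, "p1"); chk_posint(p2, "p2")
  if (!is.finite(r1) || r1 <= 0) stop("r1 must be positive", call. = FALSE)
  if (!is.finite(r2) || r2 <= 0) stop("r2 must be positive", call. = FALSE)
  if (is.null(theta)) theta <- (p1 * e1 + p2 * e2) / 2
  if (!is.finite(theta) || theta <= 0) stop("theta must be positive", call. = FALSE)
  if (theta > p1 * e1 + p2 * e2) {
    stop("theta = ", theta, " is unreachable: joint full contribution yields ",
         p1 * e1 + p2 * e2, call. = FALSE)
  }
  cfg <- structure(
    list(e1 = as.integer(e1), e2 = as.integer(e2),
         p1 = as.integer(p1), p2 = as.integer(p2),
         r1 = r1, r2 = r2, theta = theta, name = name,
         half_integer = (e1 %% 2 == 0) && (e2 %% 2 == 0)),
    class = "pgg_config")
  cfg
}

#' @export
print.pgg_config <- function(x, ...) {
  cat("Threshold public goods game <", x$name, ">\n", sep = "")
  cat(sprintf("  endowments   e = (%d, %d)\n", x$e1, x$e2))
  cat(sprintf("  productivity p = (%d, %d)\n", x$p1, x$p2))
  cat(sprintf("  rewards      r = (%g, %g)\n", x$r1, x$r2))
  cat(sprintf("  threshold    theta = %g%s\n", x$theta,
              if (!x$half_integer) "  [odd endowment: half-endowment profile non-integer]" else ""))
  invisible(x)
}

#' Canonical treatment labels
#'
#' The five treatments: a symmetric control and two levels each of
#' endowment and productivity inequality.
#' @export
TREATMENTS <- c("full_equality", "moderate_endowment", "strong_endowment",
                "moderate_productivity", "strong_productivity")

.treatment_defaults <- list(
  full_equality         = list(e1 = 12, e2 = 12, p1 = 1, p2 = 1),
  moderate_endowment    = list(e1 = 16, e2 = 8,  p1 = 1, p2 = 1),
  strong_endowment      = list(e1 = 18, e2 = 6,  p1 = 1, p2 = 1),
  moderate_productivity = list(e1 = 8,  e2 = 8,  p1 = 2, p2 = 1),
  strong_productivity   = list(e1 = 6,  e2 = 6,  p1 = 3, p2 = 1)
)

#' Build a canonical treatment configuration
#'
#' Returns the default game for one of the five canonical treatments.
#' Player 1 has twice (moderate) or three times (strong) the endowment of
#' player 2 in the endowment treatments, and twice or three times the
#' productivity in the productivity treatments; the reward is 10 for both
#' players in every treatment and the threshold follows the half-endowment
#' rule. Any field can be overridden; `theta` is re-derived from the rule
#' unless explicitly overridden.
#'
#' @param name One of [TREATMENTS].
#' @param overrides Named list of `game_config()` arguments to override.
#' @return A `pgg_config`.
#' @examples
#' make_treatment("strong_endowment")       # e = (18, 6), theta = 12
#' make_treatment("full_equality", list(e1 = 4, e2 = 4))  # theta = 4
#' @export
make_treatment <- function(name, overrides = list()) {
  if (length(name) != 1 || !name %in% TREATMENTS) {
    stop("unknown treatment '", paste(name, collapse = ","),
         "'; expected one of: ", paste(TREATMENTS, collapse = ", "),
         call. = FALSE)
  }
  args <- .treatment_defaults[[name]]
  args$r1 <- 10
  args$name <- name
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(game_config, args)
}

#' Validate a contribution profile against a configuration
#'
#' @param config A `pgg_config`.
#' @param c1,c2 Integer contributions.
#' @return Invisibly `TRUE`; errors identify the offending player.
#' @export
validate_profile <- function(config, c1, c2) {
  stopifnot(inherits(config, "pgg_config"))
  for (role in 1:2) {
    ci <- if (role == 1) c1 else c2
    ei <- if (role == 1) config$e1 else config$e2
    if (length(ci) != 1 || !is.finite(ci) || ci != round(ci) ||
        ci < 0 || ci > ei) {
      stop("player ", role, ": contribution ", deparse(ci),
           " outside {0, ..., ", ei, "}", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Collective contribution of a profile
#'
#' @inheritParams validate_profile
#' @return `p1*c1 + p2*c2`.
#' @export
collective_contribution <- function(config, c1, c2) {
  validate_profile(config, c1, c2)
  config$p1 * c1 + config$p2 * c2
}

#' Payoffs of a contribution profile
#'
#' Player `i` keeps `e_i - c_i` and earns the reward `r_i` if and only if
#' the collective contribution reaches the threshold (non-strict `>=`).
#'
#' @inheritParams validate_profile
#' @return Numeric vector `c(pi1, pi2)`.
#' @examples
#' fe <- make_treatment("full_equality")
#' payoff(fe, 6, 6)   # c(16, 16): threshold met exactly
#' payoff(fe, 0, 0)   # c(12, 12): endowments kept
#' @export
payoff <- function(config, c1, c2) {
  met <- collective_contribution(config, c1, c2) >= config$theta
  c(config$e1 - c1 + if (met) config$r1 else 0,
    config$e2 - c2 + if (met) config$r2 else 0)
}

#' Payoff matrices over the full pure-strategy space
#'
#' Row `i`, column `j` correspond to contributions `c1 = i - 1`,
#' `c2 = j - 1`.
#'
#' @param config A `pgg_config`.
#' @return List with matrices `A` (player 1) and `B` (player 2), both of
#'   dimension `(e1 + 1) x (e2 + 1)`.
#' @export
payoff_matrices <- function(config) {
  c1 <- 0:config$e1
  c2 <- 0:config$e2
  met <- outer(config$p1 * c1, config$p2 * c2, "+") >= config$theta
  list(A = (config$e1 - c1) + config$r1 * met,
       B = rep(config$e2 - c2, each = length(c1)) + config$r2 * met)
}

#' Read a game configuration from a YAML or JSON file
#'
#' The file holds keys `treatment` (optional; one of [TREATMENTS]) and/or
#' explicit fields `e1, e2, p1, p2, r1, r2, theta` (all optional when a
#' treatment is named; `theta` is derived when absent).
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return A `pgg_config`.
#' @export
read_game_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fields <- intersect(names(raw), c("e1", "e2", "p1", "p2", "r1", "r2", "theta", "name"))
  if (!is.null(raw$treatment)) {
    make_treatment(raw$treatment, overrides = raw[fields])
  } else {
    do.call(game_config, raw[fields])
  }
}
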