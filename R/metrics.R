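# Outcome metrics over session records. A "group" is one pair within one
# game; game-1 and game-2 pairs count as distinct groups.

.pair_rounds <- function(records) {
  r1 <- records[records$role == 1, c("treatment", "game", "pair_id", "round",
                                     "contribution", "collective", "success",
                                     "effective")]
  r2 <- records[records$role == 2, c("game", "pair_id", "round", "contribution")]
  names(r1)[names(r1) == "contribution"] <- "c1"
  names(r2)[names(r2) == "contribution"] <- "c2"
  m <- merge(r1, r2, by = c("game", "pair_id", "round"))
  m[order(m$game, m$pair_id, m$round), ]
}

#' Success and effectiveness rates
#'
#' A group is *successful* in a round when its collective contribution
#' meets or exceeds the threshold, and *effective* when it matches the
#' threshold exactly. Rates are computed group-first: the mean over each
#' group's rounds, then the average across groups. Per-round curves
#' aggregate across groups at each round index.
#'
#' @param records A `pgg_records` data frame.
#' @param boot Number of seeded percentile-bootstrap resamples over groups
#'   for 95% confidence intervals; 0 (default) disables them.
#' @param boot_seed Seed for the bootstrap.
#' @return List with `success_rate`, `effective_rate`, `per_group` (one
#'   row per group), `curves` (columns `round`, `success_rate`,
#'   `effective_rate`) and, when `boot > 0`, `ci` with percentile bounds.
#' @export
success_metrics <- function(records, boot = 0, boot_seed = 1L) {
  if (is.null(records) || nrow(records) == 0) stop("empty records", call. = FALSE)
  pr <- .pair_rounds(records)
  grp <- paste(pr$game, pr$pair_id)
  per_group <- data.frame(
    group = unique(grp),
    success = as.numeric(tapply(pr$success, grp, mean)[unique(grp)]),
    effective = as.numeric(tapply(pr$effective, grp, mean)[unique(grp)]))
  rd <- factor(pr$round, levels = sort(unique(pr$round)))
  curves <- data.frame(
    round = sort(unique(pr$round)),
    success_rate = as.numeric(tapply(pr$success, rd, mean)),
    effective_rate = as.numeric(tapply(pr$effective, rd, mean)))
  out <- list(success_rate = mean(per_group$success),
              effective_rate = mean(per_group$effective),
              per_group = per_group, curves = curves)
  if (boot > 0) {
    set.seed(boot_seed)
    n <- nrow(per_group)
    bs <- replicate(boot, {
      idx <- sample.int(n, n, replace = TRUE)
      c(mean(per_group$success[idx]), mean(per_group$effective[idx]))
    })
    out$ci <- list(
      success = stats::quantile(bs[1, ], c(0.025, 0.975), names = FALSE),
      effective = stats::quantile(bs[2, ], c(0.025, 0.975), names = FALSE))
  }
  out
}

#' Mean absolute and relative contributions per role
#'
#' Means over all rounds and groups; relative contributions divide by the
#' role's endowment.
#'
#' @param records A `pgg_records`.
#' @param config Optional `pgg_config` (defaults to the records' attribute).
#' @return List with numeric vectors `absolute` and `relative`, one entry
#'   per role.
#' @export
contribution_summary <- function(records, config = attr(records, "config")) {
  if (is.null(records) || nrow(records) == 0) stop("empty records", call. = FALSE)
  if (is.null(config)) stop("config required", call. = FALSE)
  absolute <- c(mean(records$contribution[records$role == 1]),
                mean(records$contribution[records$role == 2]))
  list(absolute = absolute,
       relative = absolute / c(config$e1, config$e2))
}

#' Classify failing rounds by who under-contributed
#'
#' Failing pair-rounds (collective contribution below the threshold) are
#' partitioned against the half-endowment baseline: only player 1 below
#' half, only player 2 below half, both below, or neither (`other`; an
#' anomaly for equal-productivity canonical configurations, where missing
#' the threshold forces someone below half).
#'
#' @inheritParams contribution_summary
#' @return Named integer vector over
#'   `c("only_p1_low", "only_p2_low", "both_low", "other")`.
#' @export
failure_categories <- function(records, config = attr(records, "config")) {
  if (is.null(records) || nrow(records) == 0) stop("empty records", call. = FALSE)
  if (is.null(config)) stop("config required", call. = FALSE)
  pr <- .pair_rounds(records)
  fail <- pr[!pr$success, , drop = FALSE]
  lo1 <- fail$c1 < config$e1 / 2
  lo2 <- fail$c2 < config$e2 / 2
  c(only_p1_low = sum(lo1 & !lo2),
    only_p2_low = sum(!lo1 & lo2),
    both_low = sum(lo1 & lo2),
    other = sum(!lo1 & !lo2))
}

#' Conditional probability of raising one's contribution after failure
#'
#' Among within-game, within-pair round transitions where the round
#' failed AND the player contributed less than half their endowment, the
#' empirical frequency of increasing the contribution in the next round.
#' The last round of each game has no successor and is excluded as an
#' antecedent; game-1 to game-2 transitions are never counted (new
#' partner, new role).
#'
#' @inheritParams contribution_summary
#' @return List with `probability` (NA when no transition qualifies),
#'   `numerator` and `denominator`.
#' @export
conditional_response <- function(records, config = attr(records, "config")) {
  if (is.null(records) || nrow(records) == 0) stop("empty records", call. = FALSE)
  if (is.null(config)) stop("config required", call. = FALSE)
  half <- c(config$e1 / 2, config$e2 / 2)
  rec <- records[order(records$game, records$pair_id, records$role, records$round), ]
  num <- 0L; den <- 0L
  key <- paste(rec$game, rec$pair_id, rec$role)
  for (k in unique(key)) {
    rows <- rec[key == k, ]
    role <- rows$role[1]
    nr <- nrow(rows)
    if (nr < 2) next
    for (t in seq_len(nr - 1)) {
      if (!rows$success[t] && rows$contribution[t] < half[role]) {
        den <- den + 1L
        if (rows$contribution[t + 1] > rows$contribution[t]) num <- num + 1L
      }
    }
  }
  list(probability = if (den == 0) NA_real_ else num / den,
       numerator = num, denominator = den)
}

#' Full metrics summary for one treatment's records
#'
#' @inheritParams success_metrics
#' @param config Optional `pgg_config`.
#' @return List bundling [success_metrics()], [contribution_summary()],
#'   [failure_categories()] and [conditional_response()].
#' @export
metrics_summary <- function(records, config = attr(records, "config"),
                            boot = 0, boot_seed = 1L) {
  sm <- success_metrics(records, boot = boot, boot_seed = boot_seed)
  list(treatment = unique(records$treatment),
       n_groups = nrow(sm$per_group),
       success_rate = sm$success_rate,
       effective_rate = sm$effective_rate,
       curves = sm$curves,
       ci = sm$ci,
       contributions = contribution_summary(records, config),
       failure_categories = as.list(failure_categories(records, config)),
       conditional_response = conditional_response(records, config))
}

#' Write a metrics summary as JSON and the per-round curves as CSV
#'
#' @param summary Result of [metrics_summary()].
#' @param json_path,curves_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_metrics_report <- function(summary, json_path = NULL, curves_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(summary[setdiff(names(summary), "curves")], json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(curves_path)) {
    utils::write.csv(summary$curves, curves_path, row.names = FALSE)
  }
  invisible(c(json_path, curves_path))
}
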