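test_that("best responses match hand-derived cases", {
  fe <- make_treatment("full_equality")
  mp <- make_treatment("moderate_productivity")
  expect_equal(best_responses(fe, 1, 6), 6)   # completing theta costs 6 < r
  expect_equal(best_responses(fe, 1, 0), 0)   # solo provision costs 12 > r
  expect_equal(best_responses(mp, 1, 0), 6)   # 2*6 = 12 >= theta at cost 6
  expect_error(best_responses(fe, 3, 0), "role")
  expect_error(best_responses(fe, 1, 13), "player 2")
})

test_that("is_nash matches hand-derived cases with strictness", {
  me <- make_treatment("moderate_endowment")
  mp <- make_treatment("moderate_productivity")
  fe <- make_treatment("full_equality")
  expect_equal(is_nash(me, 0, 0), list(is_equilibrium = TRUE, strictness = "strict"))
  expect_equal(is_nash(mp, 0, 0), list(is_equilibrium = FALSE, strictness = "none"))
  expect_equal(is_nash(fe, 6, 6), list(is_equilibrium = TRUE, strictness = "strict"))
  # (2,10) under full equality: player 2's deviation to 0 ties (c2 = r)
  expect_equal(is_nash(fe, 2, 10)$strictness, "weak")
})

test_that("enumerate_pure_nash reproduces the full equilibrium sets of the default treatments", {
  eq_fe <- enumerate_pure_nash(make_treatment("full_equality"))
  coop <- eq_fe[eq_fe$class == "cooperative", ]
  expect_equal(eq_fe$c1[eq_fe$class == "defective"], 0L)
  expect_equal(coop$c1, 2:10)
  expect_true(all(coop$c1 + coop$c2 == 12))

  eq_se <- enumerate_pure_nash(make_treatment("strong_endowment"))
  expect_equal(unname(as.matrix(eq_se[, c("c1", "c2")])),
               rbind(c(0, 0), c(6, 6), c(7, 5), c(8, 4), c(9, 3), c(10, 2)))

  eq_mp <- enumerate_pure_nash(make_treatment("moderate_productivity"))
  expect_true(all(eq_mp$class == "cooperative"))
  expect_equal(unname(as.matrix(eq_mp[, c("c1", "c2")])),
               rbind(c(2, 8), c(3, 6), c(4, 4), c(5, 2), c(6, 0)))
  expect_true(all(2 * eq_mp$c1 + eq_mp$c2 == 12))
})

test_that("enumerate_pure_nash agrees with the exhaustive double-loop oracle on defaults and randomized configs", {
  for (tr in TREATMENTS) {
    cfg <- make_treatment(tr)
    eq <- enumerate_pure_nash(cfg)
    oracle <- oracle_nash_set(c(cfg$e1, cfg$e2), c(cfg$p1, cfg$p2),
                              c(cfg$r1, cfg$r2), cfg$theta)
    expect_equal(unname(as.matrix(eq[, c("c1", "c2")])), unname(oracle),
                 info = tr)
  }
  set.seed(2024)
  for (rep in 1:200) {
    g <- random_small_config()
    eq <- enumerate_pure_nash(g$cfg)
    oracle <- oracle_nash_set(g$e, g$p, c(g$r, g$r), g$theta)
    got <- if (nrow(eq)) unname(as.matrix(eq[, c("c1", "c2")])) else NULL
    expect_equal(got, unname(oracle))
    # and every listed profile passes the single-profile check
    if (nrow(eq)) {
      for (k in seq_len(nrow(eq))) {
        expect_true(is_nash(g$cfg, eq$c1[k], eq$c2[k])$is_equilibrium)
      }
    }
  }
})

test_that("every cooperative equilibrium is pinned to the threshold and deterred by the reward", {
  for (tr in TREATMENTS) {
    cfg <- make_treatment(tr)
    eq <- enumerate_pure_nash(cfg)
    coop <- eq[eq$class == "cooperative", ]
    for (k in seq_len(nrow(coop))) {
      c1 <- coop$c1[k]; c2 <- coop$c2[k]
      # each unilateral one-unit decrease drops the group below theta
      if (c1 > 0) {
        expect_lt(collective_contribution(cfg, c1 - 1, c2), cfg$theta)
      }
      if (c2 > 0) {
        expect_lt(collective_contribution(cfg, c1, c2 - 1), cfg$theta)
      }
      expect_lte(c1, cfg$r1)
      expect_lte(c2, cfg$r2)
    }
    if (all(c(cfg$p1, cfg$p2) == 1)) {
      expect_true(all(coop$c1 + coop$c2 == cfg$theta))
    }
  }
})

test_that("selection heuristics match their defining conditions on the default treatments", {
  me <- make_treatment("moderate_endowment")
  se <- make_treatment("strong_endowment")
  mp <- make_treatment("moderate_productivity")
  expect_equal(unlist(select_by_heuristic(me, "ERC")[, c("c1", "c2")]),
               c(c1 = 8, c2 = 4))
  expect_equal(unlist(select_by_heuristic(se, "EAC")[, c("c1", "c2")]),
               c(c1 = 6, c2 = 6))
  mcp <- select_by_heuristic(mp, "MCP")
  expect_equal(unlist(mcp[, c("c1", "c2")]), c(c1 = 6, c2 = 0))
  expect_equal(mcp$pi1 + mcp$pi2, 30)
  # ERC equals the half-endowment profile in every canonical treatment
  for (tr in TREATMENTS) {
    cfg <- make_treatment(tr)
    sel <- select_by_heuristic(cfg, "ERC")
    expect_equal(c(sel$c1, sel$c2), c(cfg$e1 / 2, cfg$e2 / 2), info = tr)
  }
  expect_error(select_by_heuristic(me, "XYZ"))
})

test_that("EAC and ERC coincide exactly under equality and productivity inequality, and differ under endowment inequality", {
  same <- c("full_equality", "moderate_productivity", "strong_productivity")
  diff <- c("moderate_endowment", "strong_endowment")
  for (tr in same) {
    cfg <- make_treatment(tr)
    expect_equal(select_by_heuristic(cfg, "EAC"), select_by_heuristic(cfg, "ERC"),
                 info = tr)
  }
  for (tr in diff) {
    cfg <- make_treatment(tr)
    eac <- select_by_heuristic(cfg, "EAC")
    erc <- select_by_heuristic(cfg, "ERC")
    expect_false(eac$c1 == erc$c1 && eac$c2 == erc$c2, info = tr)
  }
})

test_that("heuristics with no exact integer solution return NULL, or the nearest-residual equilibrium on request", {
  # equal payoffs are impossible in the strong_endowment cooperative set:
  # the EP fallback minimises |pi1 - pi2|
  se <- make_treatment("strong_endowment")
  ep <- select_by_heuristic(se, "EP")
  expect_equal(c(ep$c1, ep$c2), c(10, 2))
  # a 5-coin game has no c1 = c2 cooperative equilibrium
  tiny <- game_config(6, 2, theta = 6, r1 = 10, name = "lopsided")
  expect_null(select_by_heuristic(tiny, "EAC"))
  near <- select_by_heuristic(tiny, "EAC", nearest = TRUE)
  expect_false(is.null(near))
  tab <- heuristic_table(se)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$heuristic, c("EAC", "ERC", "ECC", "EP", "MCP"))
})

test_that("equilibrium reports serialise to JSON with classes, payoffs and the heuristic table", {
  d <- withr::local_tempdir()
  path <- file.path(d, "eq.json")
  write_equilibrium_report(make_treatment("full_equality"), path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(rep$equilibria), 10)
  expect_setequal(unique(rep$equilibria$class), c("defective", "cooperative"))
  expect_equal(nrow(rep$heuristics), 5)
})
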