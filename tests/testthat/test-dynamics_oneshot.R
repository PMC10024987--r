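fast_params <- function(dynamic, ...) {
  dynamics_params(dynamic, time_horizon = 500, ...)
}

test_that("initial conditions: uniform, seeded-random Dirichlet, and empirical sources", {
  fe <- make_treatment("full_equality")
  u <- initial_condition(fe, "uniform")
  expect_equal(u$x, rep(1 / 13, 13))
  expect_equal(u$y, rep(1 / 13, 13))
  r1 <- initial_condition(fe, "random", seed = 11)
  r2 <- initial_condition(fe, "random", seed = 11)
  expect_identical(r1, r2)
  expect_equal(sum(r1$x), 1)
  expect_false(identical(r1, initial_condition(fe, "random", seed = 12)))
  # empirical from a point mass at half endowment
  src <- list(x = c(rep(0, 6), 1, rep(0, 6)), y = c(rep(0, 6), 2, rep(0, 6)))
  emp <- initial_condition(fe, "empirical", source = src)
  expect_equal(emp$x[7], 1)
  expect_equal(emp$y[7], 1)  # normalised
  # tabular source
  tab <- data.frame(role = c(1, 2), contribution = c(6, 6), weight = c(1, 1))
  expect_equal(initial_condition(fe, "empirical", source = tab), emp)
  expect_error(initial_condition(fe, "empirical"), "source")
  expect_error(initial_condition(fe, "empirical", source = list(x = 1, y = 1)),
               "expected 13 weights")
  expect_error(initial_condition(fe, "empirical",
                                 source = list(x = c(-1, rep(1, 12)), y = rep(1, 13))),
               "negative")
})

test_that("replicator dynamics: strict Nash point masses are stationary and uniform starts converge to Nash", {
  fe <- make_treatment("full_equality")
  tr <- run_replicator(fe, point_mass_init(fe, 6, 6),
                       dynamics_params("replicator", time_horizon = 5))
  final <- tr$states[[length(tr$states)]]
  expect_equal(final$x[7], 1)
  expect_equal(final$y[7], 1)
  # uniform start: converges, limit passes is_nash; defection wins here
  tr2 <- run_replicator(fe, initial_condition(fe, "uniform"),
                        dynamics_params("replicator", time_horizon = 200))
  expect_true(tr2$converged)
  expect_true(is_nash(fe, tr2$limit_profile[1], tr2$limit_profile[2])$is_equilibrium)
  expect_equal(modal_outcome(tr2), c(0, 0))
})

test_that("replicator states stay on the simplex along the whole trajectory", {
  mp <- make_treatment("moderate_productivity")
  tr <- run_replicator(mp, initial_condition(mp, "random", seed = 5),
                       dynamics_params("replicator", time_horizon = 100))
  for (st in tr$states) {
    expect_lt(abs(sum(st$x) - 1), 1e-9)
    expect_lt(abs(sum(st$y) - 1), 1e-9)
    expect_true(all(st$x >= 0) && all(st$y >= 0))
  }
})

test_that("best-response dynamics: stationary at strict Nash, full-step jump to the best response, simplex preserved", {
  fe <- make_treatment("full_equality")
  tr <- run_best_response(fe, point_mass_init(fe, 6, 6),
                          fast_params("best_response", step_size = 0.5))
  expect_true(tr$converged)
  expect_equal(tr$limit_profile, c(6, 6))
  # step_size 1 from (0, 6): role 1 jumps to its unique best response 6
  tr2 <- run_best_response(fe, point_mass_init(fe, 0, 6),
                           dynamics_params("best_response", step_size = 1,
                                           time_horizon = 1))
  st <- tr2$states[[length(tr2$states)]]
  expect_equal(which.max(st$x) - 1L, 6L)
  for (st in tr2$states) {
    expect_lt(abs(sum(st$x) - 1), 1e-9)
    expect_lt(abs(sum(st$y) - 1), 1e-9)
  }
})

test_that("birth-death dynamics: seeded reproducibility, simplex frequencies, strict-Nash retention at mu = 0", {
  fe <- make_treatment("full_equality")
  p <- dynamics_params("birth_death", seed = 99, time_horizon = 2000,
                       mutation_rate = 0.01)
  b1 <- run_birth_death(fe, initial_condition(fe, "uniform"), p)
  b2 <- run_birth_death(fe, initial_condition(fe, "uniform"), p)
  expect_identical(b1$states, b2$states)
  for (st in b1$states) {
    expect_lt(abs(sum(st$x) - 1), 1e-9)
    expect_true(all(st$x >= 0))
  }
  # ERC point mass with mu = 0 is absorbing: imitation cannot leave it
  p0 <- dynamics_params("birth_death", seed = 4, time_horizon = 3000,
                        mutation_rate = 0)
  b3 <- run_birth_death(fe, point_mass_init(fe, 6, 6), p0)
  final <- b3$states[[length(b3$states)]]
  expect_equal(final$x[7], 1)
  expect_equal(final$y[7], 1)
  expect_error(run_birth_death(fe, initial_condition(fe, "uniform"),
                               dynamics_params("birth_death")),
               "seed")
})

test_that("introspection dynamics: stochastic transition matrix, invariant stationary vector, uniform at beta 0", {
  se <- make_treatment("strong_endowment")
  P <- introspection_transition_matrix(se, dynamics_params("introspection",
                                                           selection_strength = 1))
  expect_equal(rowSums(P), rep(1, nrow(P)))
  pi <- introspection_stationary(se, dynamics_params("introspection",
                                                     selection_strength = 1))
  expect_equal(sum(pi), 1)
  residual <- max(abs(as.vector(pi) %*% P - as.vector(pi)))
  expect_lt(residual, 1e-10)
  # beta = 0: symmetric proposal chain, uniform stationary distribution
  pi0 <- introspection_stationary(se, dynamics_params("introspection",
                                                      selection_strength = 0))
  expect_equal(as.vector(pi0), rep(1 / length(pi0), length(pi0)), tolerance = 1e-12)
})

test_that("simulated introspection agrees with the exact stationary distribution", {
  fe <- make_treatment("full_equality")
  p <- dynamics_params("introspection", selection_strength = 1, seed = 21,
                       time_horizon = 1e6)
  sim <- introspection_stationary(fe, p, mode = "simulated")
  exact <- introspection_stationary(fe, p, mode = "exact")
  tv <- 0.5 * sum(abs(sim - exact))
  expect_lt(tv, 0.02)
  expect_error(introspection_stationary(fe, dynamics_params("introspection"),
                                        mode = "simulated"), "seed")
})

test_that("modal outcome maximises the joint weight with lexicographic tie-breaks", {
  fe <- make_treatment("full_equality")
  tr <- run_replicator(fe, point_mass_init(fe, 6, 6),
                       dynamics_params("replicator", time_horizon = 1))
  expect_equal(modal_outcome(tr), c(6, 6))
  # tie between (0,0) and (12,12): lexicographically smaller wins
  tie <- structure(list(times = 0, states = list(list(
    x = c(0.5, rep(0, 11), 0.5), y = c(0.5, rep(0, 11), 0.5))),
    converged = TRUE, limit_profile = NULL, config = fe,
    params = dynamics_params("replicator")), class = "pgg_trajectory")
  expect_equal(modal_outcome(tie), c(0, 0))
})

test_that("point-mass and tightly concentrated ERC starts keep the ERC outcome under every dynamic", {
  for (tr in TREATMENTS) {
    cfg <- make_treatment(tr)
    erc <- erc_profile(cfg)
    init <- point_mass_init(cfg, erc[1], erc[2])
    rp <- run_replicator(cfg, init, dynamics_params("replicator", time_horizon = 10))
    expect_equal(modal_outcome(rp), erc, info = tr)
    br <- run_best_response(cfg, init, fast_params("best_response", step_size = 0.5))
    expect_equal(modal_outcome(br), erc, info = tr)
    bd <- run_birth_death(cfg, init,
                          dynamics_params("birth_death", seed = 8,
                                          time_horizon = 2000, mutation_rate = 0))
    expect_equal(modal_outcome(bd), erc, info = tr)
  }
  # introspection at strong selection mostly stays at the strict ERC equilibrium
  fe <- make_treatment("full_equality")
  m <- payoff_matrices(fe)
  P <- introspection_transition_matrix(fe, dynamics_params("introspection",
                                                           selection_strength = 10))
  k_erc <- 6 * (fe$e1 + 1) + 7  # (6, 6), column-major
  expect_gt(P[k_erc, k_erc], 0.99)
})

test_that("trajectories export to tidy CSV and JSON summaries", {
  d <- withr::local_tempdir()
  fe <- make_treatment("full_equality")
  tr <- run_replicator(fe, initial_condition(fe, "uniform"),
                       dynamics_params("replicator", time_horizon = 50))
  csv <- file.path(d, "traj.csv")
  write_trajectory_csv(tr, csv)
  df <- utils::read.csv(csv)
  expect_equal(names(df), c("time", "role", "contribution", "weight"))
  s1 <- df[df$time == 0 & df$role == 1, ]
  expect_equal(sum(s1$weight), 1)
  js <- file.path(d, "traj.json")
  write_trajectory_summary(tr, js)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$modal_outcome, c(0, 0))
  expect_true(summ$converged)
})
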