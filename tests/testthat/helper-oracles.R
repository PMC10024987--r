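# Independent brute-force oracles, written against the game definition
# directly (double loops over raw parameters), deliberately not reusing
# the package's payoff-matrix machinery.

oracle_payoff <- function(e, p, r, theta, c1, c2) {
  met <- p[1] * c1 + p[2] * c2 >= theta
  c(e[1] - c1 + if (met) r[1] else 0,
    e[2] - c2 + if (met) r[2] else 0)
}

# All pure Nash profiles of a small game by exhaustive deviation checks.
oracle_nash_set <- function(e, p, r, theta) {
  out <- NULL
  for (c1 in 0:e[1]) {
    for (c2 in 0:e[2]) {
      base <- oracle_payoff(e, p, r, theta, c1, c2)
      ok <- TRUE
      for (d1 in 0:e[1]) {
        if (oracle_payoff(e, p, r, theta, d1, c2)[1] > base[1] + 1e-9) { ok <- FALSE; break }
      }
      if (ok) for (d2 in 0:e[2]) {
        if (oracle_payoff(e, p, r, theta, c1, d2)[2] > base[2] + 1e-9) { ok <- FALSE; break }
      }
      if (ok) out <- rbind(out, c(c1, c2))
    }
  }
  out
}

random_small_config <- function() {
  e <- sample(2:8, 2, replace = TRUE)
  p <- sample(1:3, 2, replace = TRUE)
  r <- sample(3:15, 1)
  theta <- sample(seq_len(p[1] * e[1] + p[2] * e[2]), 1)
  list(e = e, p = p, r = r, theta = theta,
       cfg = game_config(e[1], e[2], p[1], p[2], r1 = r, theta = theta,
                         name = "random"))
}

erc_profile <- function(cfg) c(cfg$e1 / 2, cfg$e2 / 2)

# Point-mass state pair on a profile.
point_mass_init <- function(cfg, c1, c2) {
  x <- rep(0, cfg$e1 + 1); x[c1 + 1] <- 1
  y <- rep(0, cfg$e2 + 1); y[c2 + 1] <- 1
  list(x = x, y = y)
}

# Mass 1 - spread on a profile, remainder uniform.
concentrated_init <- function(cfg, c1, c2, spread = 0.2) {
  x <- rep(spread / (cfg$e1 + 1), cfg$e1 + 1); x[c1 + 1] <- x[c1 + 1] + 1 - spread
  y <- rep(spread / (cfg$e2 + 1), cfg$e2 + 1); y[c2 + 1] <- y[c2 + 1] + 1 - spread
  list(x = x, y = y)
}
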