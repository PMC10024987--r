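# Internal dynamics engines operating on a pair of payoff matrices
# A[i, j], B[i, j]: payoffs of role-1 strategy i and role-2 strategy j.
# The one-shot module feeds contribution-level matrices; the repeated
# module feeds mean cycle payoffs over a reactive-strategy family.

.fermi <- function(delta, beta) 1 / (1 + exp(-beta * delta))

.check_simplex <- function(w, where) {
  if (any(!is.finite(w))) {
    stop("non-finite state encountered in ", where, " (integration blow-up)",
         call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-6) {
    stop("simplex drift |sum - 1| = ", format(abs(sum(w) - 1)),
         " exceeds 1e-6 in ", where, call. = FALSE)
  }
  w / sum(w)
}

# Two-population replicator equation, fixed-step RK4 with per-step
# renormalisation. Returns times, recorded states and convergence flag.
.replicator_engine <- function(A, B, x, y, dt, time_horizon, tol,
                               record_every = 100L) {
  deriv <- function(x, y) {
    fx <- drop(A %*% y)
    fy <- drop(crossprod(B, x))
    list(x = x * (fx - sum(x * fx)), y = y * (fy - sum(y * fy)))
  }
  n_steps <- ceiling(time_horizon / dt)
  times <- 0
  xs <- list(list(x = x, y = y))
  converged <- FALSE
  for (s in seq_len(n_steps)) {
    k1 <- deriv(x, y)
    k2 <- deriv(x + dt / 2 * k1$x, y + dt / 2 * k1$y)
    k3 <- deriv(x + dt / 2 * k2$x, y + dt / 2 * k2$y)
    k4 <- deriv(x + dt * k3$x, y + dt * k3$y)
    nx <- x + dt / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x)
    ny <- y + dt / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
    nx <- .check_simplex(pmax(nx, 0), "replicator")
    ny <- .check_simplex(pmax(ny, 0), "replicator")
    change <- max(max(abs(nx - x)), max(abs(ny - y))) / dt
    x <- nx; y <- ny
    if (s %% record_every == 0 || s == n_steps || change < tol) {
      times <- c(times, s * dt)
      xs[[length(xs) + 1]] <- list(x = x, y = y)
    }
    if (change < tol) { converged <- TRUE; break }
  }
  list(times = times, states = xs, converged = converged)
}

# Discrete best-response dynamics: each step moves a step_size fraction of
# each role's mass toward the uniform mixture over current best responses
# to the co-role state (ties split equally).
.best_response_engine <- function(A, B, x, y, step_size, n_steps, tol) {
  br_target <- function(f) {
    best <- f >= max(f) - 1e-9
    best / sum(best)
  }
  times <- 0
  xs <- list(list(x = x, y = y))
  converged <- FALSE
  for (s in seq_len(n_steps)) {
    tx <- br_target(drop(A %*% y))
    ty <- br_target(drop(crossprod(B, x)))
    nx <- .check_simplex((1 - step_size) * x + step_size * tx, "best_response")
    ny <- .check_simplex((1 - step_size) * y + step_size * ty, "best_response")
    change <- max(max(abs(nx - x)), max(abs(ny - y)))
    x <- nx; y <- ny
    times <- c(times, s)
    xs[[length(xs) + 1]] <- list(x = x, y = y)
    if (change < tol) { converged <- TRUE; break }
  }
  list(times = times, states = xs, converged = converged)
}

# Deterministic largest-remainder apportionment of N individuals to
# weights, so point-mass initial states map to monomorphic populations.
.apportion <- function(w, N) {
  q <- w * N
  n <- floor(q)
  short <- N - sum(n)
  if (short > 0) {
    ord <- order(q - n, decreasing = TRUE)
    n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1
  }
  as.integer(n)
}

# Pairwise-comparison (Fermi) birth-death process: two finite
# subpopulations, one per role; per step a role is chosen uniformly, a
# focal and a model individual of that role are drawn, and the focal
# imitates with Fermi probability, or mutates to a uniformly random
# strategy with probability mu.
.birth_death_engine <- function(A, B, n1, n2, beta, mu, n_steps,
                                record_every = 100L) {
  N1 <- sum(n1); N2 <- sum(n2)
  k1 <- length(n1); k2 <- length(n2)
  times <- 0
  xs <- list(list(x = n1 / N1, y = n2 / N2))
  for (s in seq_len(n_steps)) {
    role <- sample.int(2L, 1L)
    if (role == 1L) {
      f <- drop(A %*% (n2 / N2))
      pop <- rep.int(seq_len(k1), n1)
      focal <- pop[sample.int(N1, 1L)]
      if (stats::runif(1) < mu) {
        new <- sample.int(k1, 1L)
      } else {
        model <- pop[sample.int(N1, 1L)]
        new <- if (stats::runif(1) < .fermi(f[model] - f[focal], beta)) model else focal
      }
      if (new != focal) {
        n1[focal] <- n1[focal] - 1L
        n1[new] <- n1[new] + 1L
      }
    } else {
      f <- drop(crossprod(B, n1 / N1))
      pop <- rep.int(seq_len(k2), n2)
      focal <- pop[sample.int(N2, 1L)]
      if (stats::runif(1) < mu) {
        new <- sample.int(k2, 1L)
      } else {
        model <- pop[sample.int(N2, 1L)]
        new <- if (stats::runif(1) < .fermi(f[model] - f[focal], beta)) model else focal
      }
      if (new != focal) {
        n2[focal] <- n2[focal] - 1L
        n2[new] <- n2[new] + 1L
      }
    }
    if (s %% record_every == 0 || s == n_steps) {
      times <- c(times, s)
      xs[[length(xs) + 1]] <- list(x = n1 / N1, y = n2 / N2)
    }
  }
  list(times = times, states = xs, converged = FALSE)
}

# Transition matrix of introspection dynamics over joint strategy
# profiles. One player is chosen uniformly, an alternative strategy is
# proposed uniformly among the player's other strategies, and the switch
# is accepted with Fermi probability. State k indexes (i, j) column-major.
.introspection_matrix <- function(A, B, beta) {
  k1 <- nrow(A); k2 <- ncol(A)
  n <- k1 * k2
  P <- matrix(0, n, n)
  idx <- function(i, j) (j - 1L) * k1 + i
  for (j in seq_len(k2)) {
    for (i in seq_len(k1)) {
      k <- idx(i, j)
      if (k1 > 1) {
        for (i2 in seq_len(k1)[-i]) {
          P[k, idx(i2, j)] <- 0.5 / (k1 - 1) * .fermi(A[i2, j] - A[i, j], beta)
        }
      }
      if (k2 > 1) {
        for (j2 in seq_len(k2)[-j]) {
          P[k, idx(i, j2)] <- 0.5 / (k2 - 1) * .fermi(B[i, j2] - B[i, j], beta)
        }
      }
      P[k, k] <- 1 - sum(P[k, ])
    }
  }
  P
}

# Stationary distribution of an irreducible aperiodic chain by direct
# linear solve of pi P = pi with the normalisation constraint.
.stationary <- function(P) {
  n <- nrow(P)
  M <- t(P) - diag(n)
  M[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- tryCatch(solve(M, b), error = function(e) {
    stop("stationary-distribution solve failed: ", conditionMessage(e),
         call. = FALSE)
  })
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# Monte-Carlo estimate of the introspection stationary distribution from
# a single long seeded run.
.introspection_sim <- function(A, B, beta, n_steps, start = c(1L, 1L)) {
  k1 <- nrow(A); k2 <- ncol(A)
  i <- start[1]; j <- start[2]
  visits <- matrix(0, k1, k2)
  who <- sample.int(2L, n_steps, replace = TRUE)
  u_prop <- stats::runif(n_steps)
  u_acc <- stats::runif(n_steps)
  for (s in seq_len(n_steps)) {
    if (who[s] == 1L && k1 > 1) {
      alt <- floor(u_prop[s] * (k1 - 1)) + 1L
      alt <- if (alt >= i) alt + 1L else alt
      if (u_acc[s] < .fermi(A[alt, j] - A[i, j], beta)) i <- alt
    } else if (who[s] == 2L && k2 > 1) {
      alt <- floor(u_prop[s] * (k2 - 1)) + 1L
      alt <- if (alt >= j) alt + 1L else alt
      if (u_acc[s] < .fermi(B[i, alt] - B[i, j], beta)) j <- alt
    }
    visits[i, j] <- visits[i, j] + 1
  }
  visits / n_steps
}
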