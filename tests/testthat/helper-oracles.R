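# Independent oracles used across the suite.

# Closed-form payoff matrix of the five-strategy model, written out
# entry-by-entry from the interaction protocol algebra (independently of
# the package's protocol simulator).
analytic_basic_matrix <- function(game, eps, delta, p = 1) {
  Tt <- game$T; R <- game$R; P <- game$P; S <- game$S
  pd <- p * delta
  m <- rbind(
    COMP = c(R - eps / 2, R - eps, 0,  S + pd - eps, R - eps),
    C    = c(R,           R,       S,  S,            S),
    D    = c(0,           Tt,      P,  P,            P),
    FAKE = c(Tt - pd,     Tt,      P,  P,            P),
    FREE = c(R,           Tt,      P,  P,            P)
  )
  colnames(m) <- rownames(m)
  m
}

# Nine-strategy model with the cost-sharing proposer COMS and the
# share-accepting variants CS, FAKS, FRES. C/FAKE/FREE reject shared-cost
# proposals (no game, payoff 0); mixed COMP/COMS encounters role-average:
# half the time COMP proposes at full cost, half the time COMS proposes a
# shared-cost deal that COMP accepts.
analytic_sharing_matrix <- function(game, eps, delta, p = 1) {
  Tt <- game$T; R <- game$R; P <- game$P; S <- game$S
  pd <- p * delta
  m <- rbind(
    COMP = c(R - eps / 2, R - eps, 0, S + pd - eps, R - eps,
             R - 3 * eps / 4, R - eps, S + pd - eps, R - eps),
    C    = c(R, R, S, S, S,  0, R, S, S),
    D    = c(0, Tt, P, P, P, 0, Tt, P, P),
    FAKE = c(Tt - pd, Tt, P, P, P, 0, Tt, P, P),
    FREE = c(R, Tt, P, P, P, 0, Tt, P, P),
    COMS = c(R - eps / 4, 0, 0, 0, 0,
             R - eps / 2, R - eps / 2, S + pd - eps / 2, R - eps / 2),
    CS   = c(R, R, S, S, S, R - eps / 2, R, S, S),
    FAKS = c(Tt - pd, Tt, P, P, P, Tt - pd - eps / 2, Tt, P, P),
    FRES = c(R, Tt, P, P, P, R - eps / 2, Tt, P, P)
  )
  colnames(m) <- rownames(m)
  m
}

# Absorption probability at k = N starting from k = 1 of the imitation
# birth-death chain, by direct linear solve of the tridiagonal system --
# the brute-force cross-check for the closed-form fixation probability.
fixation_oracle <- function(p_aa, p_ab, p_ba, p_bb, N, beta) {
  k <- seq_len(N - 1)
  pi_a <- ((k - 1) * p_aa + (N - k) * p_ab) / (N - 1)
  pi_b <- (k * p_ba + (N - k - 1) * p_bb) / (N - 1)
  base <- (k / N) * ((N - k) / N)
  tp <- base * stats::plogis(beta * (pi_a - pi_b))
  tm <- base * stats::plogis(-beta * (pi_a - pi_b))
  # x_k = tp x_{k+1} + tm x_{k-1} + (1 - tp - tm) x_k, x_0 = 0, x_N = 1
  A <- diag(x = tp + tm, nrow = N - 1)
  for (i in seq_len(N - 2)) {
    A[i, i + 1] <- -tp[i]
    A[i + 1, i] <- -tm[i + 1]
  }
  b <- c(rep(0, N - 2), tp[N - 1])
  solve(A, b)[1]
}

# Long-run state occupancy of a finite Markov chain from a seeded random
# walk; returns frequencies and naive batch-means standard errors.
mc_occupancy <- function(M, steps, seed, n_batches = 20) {
  set.seed(seed)
  q <- nrow(M)
  cum <- t(apply(M, 1, cumsum))
  state <- sample.int(q, 1)
  visits <- matrix(0, n_batches, q)
  batch_len <- steps / n_batches
  u <- stats::runif(steps)
  for (s in seq_len(steps)) {
    state <- findInterval(u[s], cum[state, ]) + 1L
    b <- min(n_batches, 1L + (s - 1L) %/% batch_len)
    visits[b, state] <- visits[b, state] + 1
  }
  bm <- visits / batch_len
  list(freq = colMeans(bm), se = apply(bm, 2, stats::sd) / sqrt(n_batches))
}

fig1_game <- function() donation_game(2, 1)
fig1_terms <- function() commitment_terms(epsilon = 0.25, delta = 4)
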