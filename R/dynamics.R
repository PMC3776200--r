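# --- finite-population imitation dynamics (pairwise-comparison rule) --------

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fermi imitation probability
#'
#' Probability that a focal individual with fitness `f_focal` adopts the
#' strategy of a model individual with fitness `f_model` under the
#' pairwise-comparison rule: `1 / (1 + exp(-beta * (f_model - f_focal)))`.
#' `beta` is the intensity of selection: at `beta = 0` imitation is a coin
#' flip (neutral drift); as `beta` grows it becomes deterministic.
#'
#' @param f_focal,f_model Fitness (payoff) of the imitating and the
#'   imitated individual; vectorised.
#' @param beta Intensity of selection, `beta >= 0`.
#'
#' @return Imitation probability in `[0, 1]`.
#' @export
#' @examples
#' fermi_prob(1, 2, beta = 0)    # 0.5: neutral drift
#' fermi_prob(0, 10, beta = 10)  # ~1: deterministic imitation
fermi_prob <- function(f_focal, f_model, beta) {
  stopifnot(all(beta >= 0))
  stats::plogis(beta * (f_model - f_focal))
}

#' Average payoffs in a two-strategy population state
#'
#' In a well-mixed population of size `N` with `k` individuals playing A
#' and `N - k` playing B, each individual interacts with everyone else
#' (self-interaction excluded), so
#' `pi_A(k) = ((k - 1) pi_AA + (N - k) pi_AB) / (N - 1)` and
#' `pi_B(k) = (k pi_BA + (N - k - 1) pi_BB) / (N - 1)`.
#'
#' @param k Number of A-players, `1 <= k <= N - 1` (vectorised).
#' @param N Population size.
#' @param p_aa,p_ab,p_ba,p_bb Pairwise payoffs (A vs A, A vs B, ...).
#'
#' @return A tibble with columns `k`, `pi_a`, `pi_b`.
#' @export
group_payoffs <- function(k, N, p_aa, p_ab, p_ba, p_bb) {
  stopifnot(N >= 2, all(k >= 1), all(k <= N - 1))
  tibble::tibble(
    k = k,
    pi_a = ((k - 1) * p_aa + (N - k) * p_ab) / (N - 1),
    pi_b = (k * p_ba + (N - k - 1) * p_bb) / (N - 1)
  )
}

#' One-step transition probabilities of the imitation birth-death chain
#'
#' Probability that the number `k` of A-players increases or decreases by
#' one in a single update event:
#' `T+-(k) = (k/N) ((N-k)/N) / (1 + exp(-+ beta (pi_A - pi_B)))`.
#'
#' @param k Number of A-players (vectorised), `1 <= k <= N - 1`.
#' @param N Population size.
#' @param beta Intensity of selection.
#' @param pi_a,pi_b Average payoffs of A- and B-players at state `k`.
#'
#' @return A tibble with columns `k`, `t_plus`, `t_minus`.
#' @export
step_probabilities <- function(k, N, beta, pi_a, pi_b) {
  stopifnot(N >= 2, all(k >= 1), all(k <= N - 1), beta >= 0)
  base <- (k / N) * ((N - k) / N)
  d <- beta * (pi_a - pi_b)
  tibble::tibble(k = k,
                 t_plus = base * stats::plogis(d),
                 t_minus = base * stats::plogis(-d))
}

payoff_entries <- function(table, a, b) {
  M <- table$payoff
  for (s in c(a, b)) {
    if (!(s %in% rownames(M))) {
      stop("strategy '", s, "' not in table", call. = FALSE)
    }
  }
  list(aa = M[a, a], ab = M[a, b], ba = M[b, a], bb = M[b, b])
}

#' Fixation probability of a single mutant
#'
#' Probability that one individual playing `invader`, introduced into a
#' population of `N - 1` residents playing `resident`, eventually takes
#' over under the pairwise-comparison rule. Uses the closed form
#' `rho = 1 / (1 + sum_i prod_{j<=i} T-(j)/T+(j))`; the ratio telescopes to
#' `exp(-beta * sum_j (pi_A(j) - pi_B(j)))`, and the sum is accumulated in
#' log space so the result stays finite for strong selection and large
#' payoff spreads. At `beta = 0` the result is exactly `1/N`.
#'
#' @param table A [payoff_table()] covering both strategies.
#' @param invader,resident Strategy names.
#' @param N Population size (`N >= 2`).
#' @param beta Intensity of selection.
#'
#' @return The fixation probability, a number in `[0, 1]`.
#' @export
#' @examples
#' tab <- payoff_table(strategy_catalog("basic"), donation_game(2, 1),
#'                     commitment_terms(0.25, 4))
#' fixation_probability(tab, "COMP", "D", N = 100, beta = 0.1)
fixation_probability <- function(table, invader, resident, N, beta) {
  stopifnot(inherits(table, "payoff_table"), N >= 2, beta >= 0)
  p <- payoff_entries(table, invader, resident)
  k <- seq_len(N - 1)
  gp <- group_payoffs(k, N, p$aa, p$ab, p$ba, p$bb)
  cum <- cumsum(-beta * (gp$pi_a - gp$pi_b))
  exp(-logsumexp(c(0, cum)))
}

#' Risk dominance between two strategies
#'
#' Strategy A is risk-dominant over B when a lone A-mutant fixates in a
#' B-population more probably than the reverse; for any intensity of
#' selection and large populations this reduces to
#' `pi_AA + pi_AB > pi_BA + pi_BB` (strict).
#'
#' @param table A [payoff_table()].
#' @param a,b Strategy names.
#'
#' @return `TRUE` if `a` is risk-dominant over `b`.
#' @seealso [rd_margin()] for the signed margin.
#' @export
risk_dominant <- function(table, a, b) {
  rd_margin(table, a, b) > 0
}

#' Risk-dominance margin
#'
#' The signed quantity `pi_AA + pi_AB - pi_BA - pi_BB`; positive iff `a`
#' is risk-dominant over `b`.
#'
#' @inheritParams risk_dominant
#' @return A number.
#' @export
rd_margin <- function(table, a, b) {
  stopifnot(inherits(table, "payoff_table"))
  p <- payoff_entries(table, a, b)
  p$aa + p$ab - p$ba - p$bb
}

#' Small-mutation-limit Markov chain over monomorphic states
#'
#' In the limit of rare mutations the population is almost always
#' monomorphic, and evolution reduces to a Markov chain over the `q`
#' homogeneous states. A mutant of strategy `j` appears in a resident
#' population of strategy `i` with probability `1/(q - 1)` and fixates
#' with probability `rho(j, i)`, so the off-diagonal transition
#' probability is `M[i, j] = rho(j, i) / (q - 1)`; diagonals make rows sum
#' to one. The stationary distribution of this chain gives the long-run
#' fraction of time spent in each monomorphic state.
#'
#' @param table A [payoff_table()].
#' @param N Population size.
#' @param beta Intensity of selection.
#' @param strategies Optional character vector restricting/ordering the
#'   strategy set; defaults to all strategies in the table.
#'
#' @return An object of class `small_mutation_chain`: list with
#'   `strategies`, the transition matrix `M`, the `stationary`
#'   distribution, and `N`, `beta`.
#' @export
#' @examples
#' tab <- payoff_table(strategy_catalog("basic"), donation_game(2, 1),
#'                     commitment_terms(0.25, 4))
#' chain <- small_mutation_chain(tab, N = 100, beta = 0.1)
#' tidy(chain)
small_mutation_chain <- function(table, N, beta, strategies = NULL) {
  stopifnot(inherits(table, "payoff_table"))
  if (is.null(strategies)) strategies <- rownames(table$payoff)
  q <- length(strategies)
  if (q < 2) stop("need at least two strategies", call. = FALSE)
  M <- matrix(0, q, q, dimnames = list(strategies, strategies))
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      M[i, j] <- fixation_probability(table, strategies[j], strategies[i],
                                      N, beta) / (q - 1)
    }
  }
  diag(M) <- 1 - rowSums(M)
  structure(
    list(strategies = strategies, M = M,
         stationary = stationary_distribution(M), N = N, beta = beta),
    class = "small_mutation_chain"
  )
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `M` for eigenvalue 1, i.e. the normalised
#' eigenvector of `t(M)`, computed by dense eigen-decomposition; if no
#' eigenvalue lies within `1e-12` of 1 (or the selected eigenvector is not
#' single-signed), falls back to a null-space linear solve of
#' `(t(M) - I) x = 0` with the normalisation constraint appended.
#'
#' @param M A row-stochastic square matrix (rows sum to 1).
#'
#' @return A non-negative probability vector summing to 1, named after
#'   `M`'s rows, with `x %*% M = x` to within `1e-10`.
#' @export
stationary_distribution <- function(M) {
  if (inherits(M, "small_mutation_chain")) M <- M$M
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-8)) {
    stop("M must be row-stochastic", call. = FALSE)
  }
  q <- nrow(M)
  v <- NULL
  e <- eigen(t(M))
  idx <- which(abs(e$values - 1) < 1e-12)
  for (i in idx) {
    cand <- Re(e$vectors[, i])
    if (all(cand >= -1e-10) || all(cand <= 1e-10)) {
      v <- cand
      break
    }
  }
  if (is.null(v)) {
    A <- rbind(t(M) - diag(q), rep(1, q))
    v <- stats::lsfit(A, c(rep(0, q), 1), intercept = FALSE)$coefficients
  }
  v <- abs(v) / sum(abs(v))
  resid <- max(abs(drop(v %*% M) - v))
  if (resid > 1e-10) {
    stop("stationary distribution residual ", format(resid), call. = FALSE)
  }
  stats::setNames(v, rownames(M))
}

#' @export
print.small_mutation_chain <- function(x, ...) {
  cat(sprintf(
    "<small_mutation_chain> %d strategies, N = %d, beta = %g\n",
    length(x$strategies), x$N, x$beta))
  print(round(x$stationary, 4))
  invisible(x)
}

#' Tidy the stationary distribution of a small-mutation chain
#'
#' @param x A `small_mutation_chain`.
#' @param ... Unused.
#' @return A tibble with columns `strategy` and `stationary`.
#' @export
tidy.small_mutation_chain <- function(x, ...) {
  tibble::tibble(strategy = x$strategies,
                 stationary = unname(x$stationary))
}

#' One-row summary of a small-mutation chain
#'
#' @param x A `small_mutation_chain`.
#' @param ... Unused.
#' @return A tibble with the strategy count, population size, selection
#'   intensity, and the modal strategy with its stationary mass.
#' @export
glance.small_mutation_chain <- function(x, ...) {
  i <- which.max(x$stationary)
  tibble::tibble(n_strategies = length(x$strategies), pop_size = x$N,
                 beta = x$beta, top_strategy = x$strategies[i],
                 top_mass = unname(x$stationary[i]))
}
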