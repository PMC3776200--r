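# --- encounter protocol -----------------------------------------------------
#
# One pairwise interaction proceeds in stages:
#   1. proposal: a proposing strategy offers a deal (full-cost or
#      shared-cost). If both players propose, each takes the proposer role
#      with probability 1/2 and payoffs are the expectation over the roles.
#   2. response: the responder accepts per its acceptance traits. A
#      rejected proposal voids the game: both score 0.
#   3. arrangement cost: full-cost deal -> the proposer pays epsilon;
#      shared-cost deal -> each party pays epsilon/2.
#   4. play: inside a deal both use their committed move; with no deal both
#      use their uncommitted move, and if either refuses to play
#      ("no_play") both score 0.
#   5. enforcement: a committed player who defected pays delta to the
#      co-player; the transfer succeeds with probability p, so in
#      expectation the defaulter pays p*delta and the co-player receives
#      p*delta.

base_play <- function(a1, a2, game) {
  if (a1 == "no_play" || a2 == "no_play") return(c(0, 0))
  if (a1 == "C") {
    if (a2 == "C") c(game$R, game$R) else c(game$S, game$T)
  } else {
    if (a2 == "C") c(game$T, game$S) else c(game$P, game$P)
  }
}

# deal between proposer (first) and responder (second); assumes acceptance
resolve_deal <- function(proposer, responder, shared, game, terms) {
  pay <- base_play(proposer$committed, responder$committed, game)
  if (shared) {
    pay <- pay - terms$epsilon / 2
  } else {
    pay[1] <- pay[1] - terms$epsilon
  }
  pd <- terms$enforce_prob * terms$delta
  if (proposer$committed == "D") pay <- pay + c(-pd, pd)
  if (responder$committed == "D") pay <- pay + c(pd, -pd)
  pay
}

# payoffs (to s1, to s2) with s1 in the proposer role
one_role <- function(s1, s2, game, terms) {
  shared <- s1$proposes == "shared_cost"
  accepts <- if (shared) s2$accepts_shared else s2$accepts_full
  if (!accepts) return(c(0, 0))
  resolve_deal(s1, s2, shared, game, terms)
}

encounter_payoffs <- function(s1, s2, game, terms) {
  p1 <- s1$proposes != "never"
  p2 <- s2$proposes != "never"
  if (p1 && p2) {
    (one_role(s1, s2, game, terms) + rev(one_role(s2, s1, game, terms))) / 2
  } else if (p1) {
    one_role(s1, s2, game, terms)
  } else if (p2) {
    rev(one_role(s2, s1, game, terms))
  } else {
    base_play(s1$uncommitted, s2$uncommitted, game)
  }
}

payoff_matrix_internal <- function(strategies, game, terms) {
  q <- nrow(strategies)
  rows <- lapply(seq_len(q), function(i) as.list(strategies[i, ]))
  M <- matrix(0, q, q, dimnames = list(strategies$name, strategies$name))
  for (i in seq_len(q)) {
    for (j in i:q) {
      pay <- encounter_payoffs(rows[[i]], rows[[j]], game, terms)
      M[i, j] <- pay[1]
      M[j, i] <- pay[2]
    }
  }
  M
}

#' Expected payoffs of a single pairwise encounter
#'
#' Runs the commitment protocol (proposal, response, arrangement cost,
#' play, enforcement) for two strategies and returns the expected payoff
#' to each. When both strategies propose, each takes the proposer role
#' with probability one half and the result is the expectation over the
#' two role assignments.
#'
#' @param strategies A strategy tibble (see [strategy_catalog()])
#'   containing both named strategies.
#' @param s1,s2 Strategy names.
#' @param game A [game_matrix()].
#' @param terms A [commitment_terms()].
#'
#' @return A named numeric vector of length 2: expected payoff to `s1`
#'   and to `s2`.
#' @export
#' @examples
#' cat5 <- strategy_catalog("basic")
#' pairwise_payoffs(cat5, "COMP", "FAKE", donation_game(2, 1),
#'                  commitment_terms(0.25, 4))
pairwise_payoffs <- function(strategies, s1, s2, game, terms) {
  validate_strategies(strategies)
  stopifnot(inherits(game, "game_matrix"),
            inherits(terms, "commitment_terms"))
  pay <- encounter_payoffs(strategy_as_list(strategies, s1),
                           strategy_as_list(strategies, s2), game, terms)
  stats::setNames(pay, c(s1, s2))
}

#' Build the pairwise payoff table of a strategy set
#'
#' Computes the q x q matrix of expected payoffs `pi[i, j]` (payoff of
#' strategy `i` against strategy `j`) for every ordered pair, running each
#' unordered encounter once so that `pi[i, j]` and `pi[j, i]` come from the
#' same protocol evaluation.
#'
#' @inheritParams pairwise_payoffs
#'
#' @return An object of class `payoff_table`: a list with the strategy
#'   tibble, the payoff matrix (`$payoff`, with strategy dimnames), and the
#'   game and terms used.
#' @export
#' @examples
#' tab <- payoff_table(strategy_catalog("basic"), donation_game(2, 1),
#'                     commitment_terms(0.25, 4))
#' tab$payoff
payoff_table <- function(strategies, game, terms) {
  validate_strategies(strategies)
  stopifnot(inherits(game, "game_matrix"),
            inherits(terms, "commitment_terms"))
  if (nrow(strategies) == 0) stop("empty strategy set", call. = FALSE)
  structure(
    list(strategies = strategies,
         payoff = payoff_matrix_internal(strategies, game, terms),
         game = game, terms = terms),
    class = "payoff_table"
  )
}

#' @export
print.payoff_table <- function(x, digits = 4, ...) {
  cat(sprintf("<payoff_table> %d strategies; T=%g R=%g P=%g S=%g; ",
              nrow(x$strategies), x$game$T, x$game$R, x$game$P, x$game$S))
  cat(sprintf("epsilon=%g delta=%g p=%g\n",
              x$terms$epsilon, x$terms$delta, x$terms$enforce_prob))
  print(round(x$payoff, digits))
  invisible(x)
}

#' @export
as.matrix.payoff_table <- function(x, ...) x$payoff

#' Tidy a payoff table into long format
#'
#' @param x A `payoff_table`.
#' @param ... Unused.
#' @return A tibble with columns `strategy` (row player), `opponent`
#'   (column player) and `payoff` (expected payoff to the row player).
#' @export
tidy.payoff_table <- function(x, ...) {
  M <- x$payoff
  tidyr::expand_grid(strategy = rownames(M), opponent = colnames(M)) |>
    dplyr::mutate(payoff = as.vector(t(M)))
}

#' Payoff table of the costly-punishment comparison model
#'
#' A three-strategy model with no prior agreement: next to `C` and `D`, the
#' costly punisher `CP` cooperates always and, after a game against a
#' defector, pays `epsilon` to impose a fine `delta` on it. The `C`/`D`
#' sub-game is the plain Prisoner's Dilemma, unaffected by the punishment
#' parameters.
#'
#' @param game A [game_matrix()].
#' @param epsilon Cost of punishing, per punished opponent.
#' @param delta Fine imposed on the punished defector.
#'
#' @return A `payoff_table` over strategies `CP`, `C`, `D`. Its
#'   `strategies` tibble carries placeholder commitment traits (the model
#'   has no proposals); the payoff matrix is authoritative.
#' @export
cp_payoff_table <- function(game, epsilon, delta) {
  stopifnot(inherits(game, "game_matrix"),
            is.finite(epsilon), epsilon >= 0,
            is.finite(delta), delta >= 0)
  strategies <- dplyr::bind_rows(
    new_strategy_row("CP", "never", FALSE, FALSE, "C", "C"),
    new_strategy_row("C",  "never", TRUE,  FALSE, "C", "C"),
    new_strategy_row("D",  "never", FALSE, FALSE, "D", "D")
  )
  M <- matrix(c(
    game$R, game$R, game$S - epsilon,
    game$R, game$R, game$S,
    game$T - delta, game$T, game$P
  ), nrow = 3, byrow = TRUE,
  dimnames = list(strategies$name, strategies$name))
  structure(list(strategies = strategies, payoff = M, game = game,
                 terms = commitment_terms(epsilon, delta, 1)),
            class = "payoff_table")
}
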