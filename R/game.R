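#' Define a symmetric two-player game by its four payoffs
#'
#' Constructs the payoff structure of a symmetric 2x2 game from the
#' temptation `T`, reward `R`, punishment `P` and sucker's payoff `S`.
#' By default the Prisoner's Dilemma ordering `T > R > P > S` is enforced,
#' since the commitment analysis is formulated for social dilemmas; set
#' `check_pd = FALSE` to describe a general game.
#'
#' @param T Temptation to defect (payoff for unilateral defection).
#' @param R Reward for mutual cooperation.
#' @param P Punishment for mutual defection.
#' @param S Sucker's payoff (unilateral cooperation).
#' @param check_pd Require the Prisoner's Dilemma ordering `T > R > P > S`?
#'
#' @return An object of class `game_matrix`: a named list with elements
#'   `T`, `R`, `P`, `S`.
#' @seealso [donation_game()] for the benefit/cost parameterisation.
#' @export
#' @examples
#' game_matrix(T = 2, R = 1, P = 0, S = -1)
game_matrix <- function(T, R, P, S, check_pd = TRUE) {
  vals <- c(T = T, R = R, P = P, S = S)
  if (!all(is.finite(vals))) {
    stop("game payoffs must be finite numbers", call. = FALSE)
  }
  if (check_pd && !(T > R && R > P && P > S)) {
    stop("Prisoner's Dilemma ordering T > R > P > S violated; ",
         "use check_pd = FALSE for general games", call. = FALSE)
  }
  structure(list(T = T, R = R, P = P, S = S), class = "game_matrix")
}

#' Donation-game parameterisation of the Prisoner's Dilemma
#'
#' The Donation game gives a cooperator's partner a benefit `b` at a
#' personal cost `c`, i.e. `T = b`, `R = b - c`, `P = 0`, `S = -c`,
#' with `b > c > 0`.
#'
#' @param b Benefit of cooperation received by the partner (`b > c`).
#' @param c Cost of cooperation paid by the cooperator (`c > 0`).
#'
#' @return A `game_matrix` object.
#' @export
#' @examples
#' donation_game(b = 2, c = 1) # T = 2, R = 1, P = 0, S = -1
donation_game <- function(b, c) {
  if (!is.finite(b) || !is.finite(c) || c <= 0 || b <= c) {
    stop("Donation game requires b > c > 0", call. = FALSE)
  }
  game_matrix(T = b, R = b - c, P = 0, S = -c)
}

#' @export
print.game_matrix <- function(x, ...) {
  cat(sprintf("<game_matrix> T = %g, R = %g, P = %g, S = %g\n",
              x$T, x$R, x$P, x$S))
  invisible(x)
}

#' Terms of a commitment deal
#'
#' The three parameters that define a pre-play commitment: the arrangement
#' cost `epsilon` paid to set the deal up, the compensation `delta` a
#' defaulting party owes its committed co-player, and the probability
#' `enforce_prob` that the compensation is actually collected (1 means a
#' society that always resolves the conflict; smaller values model partial
#' enforcement, where the proposer receives `p * delta` on average).
#'
#' @param epsilon Arrangement cost, `epsilon >= 0`.
#' @param delta Compensation owed by a committed defector, `delta >= 0`.
#' @param enforce_prob Probability the compensation is collected, in
#'   `[0, 1]`. Both the defaulter's payment and the victim's receipt scale
#'   with it.
#'
#' @return An object of class `commitment_terms`.
#' @export
#' @examples
#' commitment_terms(epsilon = 0.25, delta = 4)
commitment_terms <- function(epsilon = 0.25, delta = 4, enforce_prob = 1) {
  if (!is.finite(epsilon) || epsilon < 0) {
    stop("epsilon must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(delta) || delta < 0) {
    stop("delta must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(enforce_prob) || enforce_prob < 0 || enforce_prob > 1) {
    stop("enforce_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(epsilon = epsilon, delta = delta,
                 enforce_prob = enforce_prob),
            class = "commitment_terms")
}

#' @export
print.commitment_terms <- function(x, ...) {
  cat(sprintf("<commitment_terms> epsilon = %g, delta = %g, p = %g\n",
              x$epsilon, x$delta, x$enforce_prob))
  invisible(x)
}
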