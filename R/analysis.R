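#' Payoff table for one of the named models
#'
#' Convenience wrapper building the [payoff_table()] of the `"basic"`
#' (5-strategy) or `"sharing"` (9-strategy) commitment model, or of the
#' `"cp"` costly-punishment comparison model.
#'
#' @param model `"basic"`, `"sharing"` or `"cp"`.
#' @param game A [game_matrix()].
#' @param terms A [commitment_terms()] (for `"cp"` its `epsilon`/`delta`
#'   are the punishment cost and fine; `enforce_prob` is ignored).
#'
#' @return A `payoff_table`.
#' @export
model_payoff_table <- function(model = c("basic", "sharing", "cp"),
                               game, terms) {
  model <- match.arg(model)
  if (model == "cp") {
    cp_payoff_table(game, terms$epsilon, terms$delta)
  } else {
    payoff_table(strategy_catalog(model), game, terms)
  }
}

min_margin_table <- function(table, focal, opponents) {
  min(vapply(opponents, function(o) rd_margin(table, focal, o),
             numeric(1)))
}

boundary_subset <- function(focal, opponents, strategies) {
  if (is.null(strategies)) strategies <- strategy_catalog("sharing")
  validate_strategies(strategies)
  need <- unique(c(focal, opponents))
  missing <- setdiff(need, strategies$name)
  if (length(missing) > 0) {
    stop("strategies not in catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  strategies[match(need, strategies$name), ]
}

certify_boundary <- function(margin_fn, x_star, tol) {
  lo <- margin_fn(max(0, x_star - 10 * tol))
  hi <- margin_fn(x_star + 10 * tol)
  if (!(lo * hi < 0)) {
    stop("boundary not certified: risk dominance does not flip across it",
         call. = FALSE)
  }
  invisible(TRUE)
}

boundary_result <- function(focal, opponents, parameter, value, tol) {
  tibble::tibble(focal = focal,
                 opponents = paste(opponents, collapse = ","),
                 parameter = parameter, value = value, tol = tol)
}

#' Largest arrangement cost at which a proposer stays risk-dominant
#'
#' Finds, by bisection, the arrangement cost `epsilon*` at which the focal
#' proposing strategy loses risk dominance against the worst of the given
#' opponents (the minimum risk-dominance margin over the opponents crosses
#' zero). The compensation `delta` must be generous enough that the
#' delta-condition is not the binding constraint; if the focal strategy is
#' not risk-dominant even at `epsilon = 0` an error is raised.
#'
#' @param focal Name of the proposing strategy (e.g. `"COMP"`, `"COMS"`).
#' @param opponents Character vector of opponent strategy names.
#' @param game A [game_matrix()].
#' @param delta Compensation level (held fixed).
#' @param p Enforcement probability.
#' @param strategies Strategy tibble covering all names; defaults to the
#'   sharing catalog.
#' @param tol Bisection tolerance (bracket width).
#' @param upper Upper end of the scanned `epsilon` range; defaults to a
#'   multiple of the game's payoff spread.
#'
#' @return A one-row tibble with columns `focal`, `opponents`,
#'   `parameter`, `value` (the boundary), `tol`. The flip of
#'   [risk_dominant()] across the boundary is verified before returning.
#' @export
#' @examples
#' epsilon_boundary("COMP", c("D", "FAKE", "FREE"), donation_game(2, 1),
#'                  delta = 4) # value = 2/3
epsilon_boundary <- function(focal, opponents, game, delta, p = 1,
                             strategies = NULL, tol = 1e-9,
                             upper = NULL) {
  strat <- boundary_subset(focal, opponents, strategies)
  if (is.null(upper)) upper <- 10 * max(1, abs(game$R - game$P))
  margin <- function(eps) {
    tab <- payoff_table(strat, game, commitment_terms(eps, delta, p))
    min_margin_table(tab, focal, opponents)
  }
  if (margin(0) <= 0) {
    stop("focal strategy is not risk-dominant even at epsilon = 0; ",
         "the delta-condition is binding", call. = FALSE)
  }
  if (margin(upper) >= 0) {
    stop("no sign change in [0, ", upper, "]; increase `upper`",
         call. = FALSE)
  }
  root <- stats::uniroot(margin, c(0, upper), tol = tol)$root
  certify_boundary(margin, root, tol)
  boundary_result(focal, opponents, "epsilon", root, tol)
}

#' Smallest compensation making a proposer risk-dominant
#'
#' Finds, by bisection, the minimal compensation `delta*` at which the
#' focal strategy becomes risk-dominant against every listed opponent, at
#' a fixed arrangement cost `epsilon`. Errors if no compensation can
#' achieve this (i.e. `epsilon` already exceeds its own boundary).
#'
#' @inheritParams epsilon_boundary
#' @param epsilon Arrangement cost (held fixed).
#' @param upper Upper end of the scanned `delta` range.
#'
#' @return A one-row tibble as in [epsilon_boundary()] with
#'   `parameter = "delta"`. If the focal strategy is risk-dominant even at
#'   `delta = 0` the boundary is reported as 0.
#' @export
#' @examples
#' delta_boundary("COMP", "FAKE", donation_game(2, 1), epsilon = 0)
#' # value = 1: the cost of cooperation
delta_boundary <- function(focal, opponents, game, epsilon, p = 1,
                           strategies = NULL, tol = 1e-9, upper = NULL) {
  strat <- boundary_subset(focal, opponents, strategies)
  if (is.null(upper)) {
    upper <- 10 * max(1, abs(game$T - game$S) + abs(game$R - game$P) +
                        epsilon)
  }
  margin <- function(delta) {
    tab <- payoff_table(strat, game, commitment_terms(epsilon, delta, p))
    min_margin_table(tab, focal, opponents)
  }
  if (margin(upper) <= 0) {
    stop("no compensation in [0, ", upper, "] makes the focal strategy ",
         "risk-dominant; epsilon exceeds its own boundary", call. = FALSE)
  }
  if (margin(0) > 0) {
    return(boundary_result(focal, opponents, "delta", 0, tol))
  }
  root <- stats::uniroot(margin, c(0, upper), tol = tol)$root
  certify_boundary(margin, root, tol)
  boundary_result(focal, opponents, "delta", root, tol)
}

#' Stationary frequencies over a grid of commitment terms
#'
#' For every combination of arrangement cost and compensation on the grid,
#' builds the model's payoff table, the small-mutation chain, and its
#' stationary distribution, and returns everything in long format — the
#' data behind frequency-versus-cost curves and cost-compensation
#' heatmaps.
#'
#' @param model `"basic"`, `"sharing"` or `"cp"`.
#' @param game A [game_matrix()].
#' @param epsilon_grid,delta_grid Non-negative numeric grids.
#' @param N Population size.
#' @param beta Intensity of selection.
#' @param p Enforcement probability.
#'
#' @return A tibble with columns `epsilon`, `delta`, `strategy`,
#'   `frequency`; frequencies sum to 1 at every grid point.
#' @export
#' @examples
#' sweep_stationary("basic", donation_game(2, 1),
#'                  epsilon_grid = c(0.25, 1), delta_grid = 4,
#'                  N = 100, beta = 0.1)
sweep_stationary <- function(model, game, epsilon_grid, delta_grid,
                             N = 100, beta = 0.1, p = 1) {
  stopifnot(length(epsilon_grid) > 0, length(delta_grid) > 0,
            all(epsilon_grid >= 0), all(delta_grid >= 0))
  grid <- tidyr::expand_grid(epsilon = epsilon_grid, delta = delta_grid)
  purrr::pmap_dfr(grid, function(epsilon, delta) {
    tab <- model_payoff_table(model, game,
                              commitment_terms(epsilon, delta, p))
    chain <- small_mutation_chain(tab, N, beta)
    tibble::tibble(epsilon = epsilon, delta = delta,
                   strategy = chain$strategies,
                   frequency = unname(chain$stationary))
  })
}

#' Fixation probabilities for every ordered strategy pair
#'
#' Computes the fixation probability of a single `to`-mutant in a resident
#' population of `from`-players for every ordered pair in the table,
#' reporting each both raw and as a multiple of the neutral probability
#' `1/N`. A transition is flagged advantageous when `rho > 1/N` beyond
#' `tol`, neutral when `|rho - 1/N| <= tol`.
#'
#' @param table A [payoff_table()].
#' @param N Population size.
#' @param beta Intensity of selection.
#' @param tol Tolerance for the neutral/advantageous classification.
#'
#' @return A tibble with columns `from`, `to`, `rho`, `rho_over_neutral`
#'   (`rho * N`), `advantageous`, `neutral`.
#' @export
transition_graph <- function(table, N, beta, tol = 1e-12) {
  stopifnot(inherits(table, "payoff_table"))
  strategies <- rownames(table$payoff)
  pairs <- tidyr::expand_grid(from = strategies, to = strategies) |>
    dplyr::filter(.data$from != .data$to)
  rho <- purrr::map2_dbl(pairs$from, pairs$to, function(fr, to) {
    fixation_probability(table, to, fr, N, beta)
  })
  pairs |>
    dplyr::mutate(
      rho = rho,
      rho_over_neutral = rho * N,
      advantageous = rho > 1 / N + tol,
      neutral = abs(rho - 1 / N) <= tol
    )
}
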