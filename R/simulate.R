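#' Agent-based simulation of imitation with mutation
#'
#' Simulates the full stochastic process the analytic machinery
#' approximates: a well-mixed population of `N` agents updated one event
#' at a time. With probability `mu` a uniformly chosen agent mutates to a
#' uniformly chosen different strategy; otherwise a random agent imitates
#' another random agent's strategy with the Fermi probability
#' [fermi_prob()] computed from their current average payoffs
#' (self-interaction excluded, recomputed from the live strategy counts at
#' every event). At small `mu` the time-averaged strategy frequencies
#' converge to the stationary distribution of the small-mutation chain;
#' at larger `mu` the simulation explores what the analytic limit cannot.
#'
#' Standard errors of the time-averaged frequencies use batch means
#' (default 20 batches) since consecutive samples are strongly
#' autocorrelated.
#'
#' @param table A [payoff_table()] covering the simulated strategies.
#' @param N Population size.
#' @param beta Intensity of selection.
#' @param mu Mutation probability per update event.
#' @param events Number of update events.
#' @param burn_in Initial events discarded from the time averages
#'   (default: 10% of `events`).
#' @param init Named integer vector of initial strategy counts summing to
#'   `N`; default splits the population as evenly as possible.
#' @param seed Optional integer seed (applied with [set.seed()]); two runs
#'   with the same seed are identical.
#' @param n_batches Number of batches for the batch-means standard errors.
#' @param thin Trajectory snapshot interval in events (default keeps about
#'   2000 snapshots).
#'
#' @return An object of class `imitation_sim` with elements `strategies`,
#'   `frequency` (time-averaged, named), `se` (batch-means standard
#'   errors), `batch_means` (batches x strategies), `trajectory` (tibble
#'   of sampled counts), and `config`.
#' @export
#' @examples
#' tab <- payoff_table(strategy_catalog("basic"), donation_game(2, 1),
#'                     commitment_terms(0.25, 4))
#' sim <- simulate_imitation(tab, N = 50, beta = 0.1, mu = 1e-2,
#'                           events = 2e4, seed = 1)
#' tidy(sim)
simulate_imitation <- function(table, N, beta, mu, events,
                               burn_in = floor(events / 10), init = NULL,
                               seed = NULL, n_batches = 20,
                               thin = max(1L, floor(events / 2000))) {
  stopifnot(inherits(table, "payoff_table"), N >= 2, beta >= 0,
            mu >= 0, mu <= 1, events > burn_in, burn_in >= 0,
            n_batches >= 2)
  strategies <- rownames(table$payoff)
  q <- length(strategies)
  if (is.null(init)) {
    init <- rep(N %/% q, q)
    extra <- N - sum(init)
    if (extra > 0) init[seq_len(extra)] <- init[seq_len(extra)] + 1L
    names(init) <- strategies
  } else {
    if (is.null(names(init))) names(init) <- strategies
    init <- init[strategies]
    if (anyNA(init) || sum(init) != N || any(init < 0)) {
      stop("init must be non-negative counts over the table's strategies ",
           "summing to N", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  res <- simulate_core(table$payoff, as.integer(init), beta, mu,
                       as.integer(events), as.integer(burn_in),
                       as.integer(n_batches), as.integer(thin))
  bm <- sweep(res$batch_sums, 1, pmax(res$batch_events, 1L) * N, "/")
  colnames(bm) <- strategies
  freq <- colMeans(bm)
  se <- apply(bm, 2, stats::sd) / sqrt(n_batches)
  ns <- res$n_snapshots
  traj <- tibble::as_tibble(stats::setNames(
    as.data.frame(res$trajectory[seq_len(ns), , drop = FALSE]), strategies))
  traj <- dplyr::bind_cols(
    tibble::tibble(event = res$trajectory_event[seq_len(ns)]), traj)
  structure(
    list(strategies = strategies, frequency = freq, se = se,
         batch_means = bm, trajectory = traj,
         final_counts = stats::setNames(res$final_counts, strategies),
         config = list(N = N, beta = beta, mu = mu, events = events,
                       burn_in = burn_in, init = init, seed = seed,
                       n_batches = n_batches, thin = thin)),
    class = "imitation_sim"
  )
}

#' @export
print.imitation_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<imitation_sim> N = %d, beta = %g, mu = %g, %g events (%g burn-in)\n",
    cfg$N, cfg$beta, cfg$mu, cfg$events, cfg$burn_in))
  print(round(x$frequency, 4))
  invisible(x)
}

#' Tidy the time-averaged frequencies of an agent-based run
#'
#' @param x An `imitation_sim`.
#' @param ... Unused.
#' @return A tibble with columns `strategy`, `frequency`, `se`.
#' @export
tidy.imitation_sim <- function(x, ...) {
  tibble::tibble(strategy = x$strategies,
                 frequency = unname(x$frequency),
                 se = unname(x$se))
}

#' One-row summary of an agent-based run
#'
#' @param x An `imitation_sim`.
#' @param ... Unused.
#' @return A tibble echoing the run configuration and the modal strategy.
#' @export
glance.imitation_sim <- function(x, ...) {
  cfg <- x$config
  i <- which.max(x$frequency)
  tibble::tibble(pop_size = cfg$N, beta = cfg$beta, mu = cfg$mu,
                 events = cfg$events, burn_in = cfg$burn_in,
                 seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
                 top_strategy = x$strategies[i],
                 top_frequency = unname(x$frequency[i]))
}
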