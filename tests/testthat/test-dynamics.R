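test_that("the Fermi rule has its limiting behaviours", {
  expect_equal(fermi_prob(3, 7, beta = 0), 0.5)
  expect_equal(fermi_prob(2.2, 2.2, beta = 5), 0.5)
  expect_gt(fermi_prob(0, 1, beta = 50), 1 - 1e-10)
  expect_lt(fermi_prob(1, 0, beta = 50), 1e-10)
  # monotone in the fitness difference
  d <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(fermi_prob(0, d, beta = 0.7)) > 0))
  expect_error(fermi_prob(0, 1, beta = -1))
})

test_that("average payoffs exclude self-interaction", {
  # constant game: everyone earns the constant regardless of composition
  gp <- group_payoffs(1:9, 10, 3, 3, 3, 3)
  expect_true(all(gp$pi_a == 3) && all(gp$pi_b == 3))
  # a lone mutant meets only residents
  gp1 <- group_payoffs(1, 50, 100, 7, 0, 0)
  expect_equal(gp1$pi_a, 7)
  # hand-computed three-player case
  gp2 <- group_payoffs(2, 3, 3, 1, 2, 0)
  expect_equal(gp2$pi_a, 2)
  expect_equal(gp2$pi_b, 2)
  expect_error(group_payoffs(0, 10, 1, 1, 1, 1))
  expect_error(group_payoffs(10, 10, 1, 1, 1, 1))
})

test_that("step probabilities follow the pairwise-comparison form", {
  # neutral drift: both directions equal k(N-k)/(2 N^2)
  sp <- step_probabilities(1:9, 10, 0, pi_a = runif(9), pi_b = runif(9))
  expect_equal(sp$t_plus, (1:9) * (9:1) / 200)
  expect_equal(sp$t_minus, sp$t_plus)
  # equal payoffs: symmetric at any beta
  sp2 <- step_probabilities(3, 10, 2.5, 1, 1)
  expect_equal(sp2$t_plus, sp2$t_minus)
  # detailed-balance ratio T+/T- = exp(beta * dpi)
  sp3 <- step_probabilities(5, 10, 0.1, 2, 1)
  expect_equal(sp3$t_plus / sp3$t_minus, exp(0.1))
  # bounded by 1/2 and vanishing at the absorbing ends is implied by form
  expect_true(all(sp$t_plus <= 0.5 & sp$t_plus >= 0))
})

test_that("fixation probability is 1/N under neutrality", {
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  for (N in c(2, 10, 100)) {
    for (pair in list(c("COMP", "D"), c("FAKE", "C"), c("FREE", "FAKE"))) {
      expect_equal(fixation_probability(tab, pair[1], pair[2], N, 0),
                   1 / N, tolerance = 1e-14)
    }
  }
  # equal payoff rows stay neutral at positive selection strength
  expect_equal(fixation_probability(tab, "D", "FAKE", 60, 0.7), 1 / 60,
               tolerance = 1e-12)
})

test_that("closed-form fixation matches the absorbing-chain solve", {
  set.seed(7)
  strategies <- strategy_catalog("basic")[1:2, ]
  strategies$name <- c("A", "B")
  for (rep in 1:8) {
    M <- matrix(runif(4, -2, 2), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    tab <- structure(list(strategies = strategies, payoff = M,
                          game = fig1_game(), terms = fig1_terms()),
                     class = "payoff_table")
    for (N in c(2, 5, 13)) {
      for (beta in c(0, 0.3, 2)) {
        expect_equal(
          fixation_probability(tab, "A", "B", N, beta),
          fixation_oracle(M["A", "A"], M["A", "B"],
                          M["B", "A"], M["B", "B"], N, beta),
          tolerance = 1e-10)
      }
    }
  }
})

test_that("fixation stays finite and bounded under strong selection", {
  strategies <- strategy_catalog("basic")[1:2, ]
  strategies$name <- c("A", "B")
  M <- matrix(c(1000, -1000, 500, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  tab <- structure(list(strategies = strategies, payoff = M,
                        game = fig1_game(), terms = fig1_terms()),
                   class = "payoff_table")
  for (beta in c(0.1, 1, 10)) {
    r1 <- fixation_probability(tab, "A", "B", 200, beta)
    r2 <- fixation_probability(tab, "B", "A", 200, beta)
    expect_true(is.finite(r1) && r1 >= 0 && r1 <= 1)
    expect_true(is.finite(r2) && r2 >= 0 && r2 <= 1)
  }
})

test_that("risk dominance follows the summed-payoff criterion", {
  g <- fig1_game()
  tab1 <- payoff_table(strategy_catalog("basic"), g,
                       commitment_terms(0.5, 4))
  expect_true(risk_dominant(tab1, "COMP", "FREE"))
  tab2 <- payoff_table(strategy_catalog("basic"), g,
                       commitment_terms(1.0, 4))
  expect_false(risk_dominant(tab2, "COMP", "FREE"))
  # never both directions, never against itself
  for (a in c("COMP", "C", "D")) {
    expect_false(risk_dominant(tab1, a, a))
    for (b in c("FAKE", "FREE")) {
      expect_false(risk_dominant(tab1, a, b) && risk_dominant(tab1, b, a))
    }
  }
})

test_that("risk dominance agrees with the fixation-probability ordering", {
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  nm <- rownames(tab$payoff)
  for (a in nm) {
    for (b in nm) {
      if (a == b) next
      rab <- fixation_probability(tab, a, b, 100, 0.1)
      rba <- fixation_probability(tab, b, a, 100, 0.1)
      if (risk_dominant(tab, a, b)) expect_gt(rab, rba)
      if (risk_dominant(tab, b, a)) expect_gt(rba, rab)
    }
  }
})

test_that("small-mutation chain is a proper Markov chain", {
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  chain <- small_mutation_chain(tab, 100, 0.1)
  expect_equal(rowSums(chain$M), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(chain$M >= 0))
  expect_equal(sum(chain$stationary), 1)
  expect_equal(drop(chain$stationary %*% chain$M), chain$stationary,
               tolerance = 1e-10)
  # neutral chain: uniform off-diagonals 1/(N(q-1)), uniform stationary
  neutral <- small_mutation_chain(tab, 50, 0)
  off <- neutral$M[row(neutral$M) != col(neutral$M)]
  expect_equal(off, rep(1 / (50 * 4), 20), ignore_attr = TRUE)
  expect_equal(unname(neutral$stationary), rep(0.2, 5))
  # two strategies: the chain holds exactly the two fixation probabilities
  pairchain <- small_mutation_chain(tab, 100, 0.1,
                                    strategies = c("COMP", "D"))
  expect_equal(pairchain$M["COMP", "D"],
               fixation_probability(tab, "D", "COMP", 100, 0.1))
  expect_equal(pairchain$M["D", "COMP"],
               fixation_probability(tab, "COMP", "D", 100, 0.1))
})

test_that("stationary distribution is permutation-equivariant", {
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  chain <- small_mutation_chain(tab, 100, 0.1)
  perm <- c("FREE", "C", "COMP", "FAKE", "D")
  chain_p <- small_mutation_chain(tab, 100, 0.1, strategies = perm)
  expect_equal(chain_p$stationary[names(chain$stationary)],
               chain$stationary, tolerance = 1e-10)
})

test_that("stationary distribution solves known cases and the walk", {
  # doubly stochastic: uniform
  M <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), 3, byrow = TRUE)
  expect_equal(unname(stationary_distribution(M)), rep(1 / 3, 3))
  expect_error(stationary_distribution(matrix(c(1, 1, 0, 1), 2)),
               "row-stochastic")
  # seeded random-walk occupancy agrees within 3 standard errors
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  chain <- small_mutation_chain(tab, 100, 0.1)
  walk <- mc_occupancy(chain$M, steps = 1e6, seed = 11)
  expect_true(all(abs(walk$freq - chain$stationary) <=
                    3 * pmax(walk$se, 1e-4)))
})

test_that("tidy and glance summarise chains", {
  tab <- payoff_table(strategy_catalog("basic"), fig1_game(), fig1_terms())
  chain <- small_mutation_chain(tab, 100, 0.1)
  td <- tidy(chain)
  expect_equal(td$strategy, chain$strategies)
  expect_equal(sum(td$stationary), 1)
  gl <- glance(chain)
  expect_equal(gl$top_strategy, "COMP")
  expect_equal(gl$pop_size, 100)
})
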