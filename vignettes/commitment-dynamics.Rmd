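---
title: "Commitment strategies in the one-shot Prisoner's Dilemma: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commitment strategies in the one-shot Prisoner's Dilemma: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commitpd)
```

## The interaction protocol

`commitpd` treats strategies as behavioural rules, not payoff rows. A
strategy is a five-trait tuple — whether it proposes a commitment (at
full or shared cost), whether it accepts full-cost and shared-cost
proposals from others, its move inside an accepted deal, and its move
when no deal is active (possibly refusing to play). Every pairwise
payoff is *derived* by executing the protocol:

1. **Proposal.** A proposing strategy offers the deal. If both players
   propose, each takes the proposer role with probability 1/2 and the
   payoffs are the expectation over the two role assignments — this is
   why two full-cost proposers each end up paying the arrangement cost
   ε only half of the time, an implicit form of cost sharing worth
   `R − ε/2` each.
2. **Response.** The responder accepts or rejects according to its
   acceptance traits. A rejected proposal voids the game: both sides
   score 0. A consequence we lean on during enumeration: a proposing
   strategy can never find itself playing *uncommitted*, so its
   "uncommitted move" trait is unreachable.
3. **Arrangement cost.** In an accepted full-cost deal the proposer
   pays ε; in an accepted shared-cost deal each party pays ε/2. The
   cost is sunk only on acceptance — a proposer whose offer is refused
   keeps ε. This keeps free-riders (who accept deals but never pay for
   them) strictly better off than proposers as ε grows, which is the
   mechanism behind the regime change along the cost axis.
4. **Play.** Committed parties use their committed move; otherwise both
   use their uncommitted move, and if either refuses ("no_play") the
   game does not happen.
5. **Enforcement.** A committed player who defected owes the co-player
   the compensation δ. The transfer succeeds with probability `p`
   (default 1), and *both* sides of the ledger scale with it: the
   defaulter pays `p·δ` in expectation and the victim receives `p·δ`.
   The alternative — defaulter always pays, victim receives `p·δ` —
   would make failed enforcement a money sink; we model an
   unresolved conflict as collecting nothing from anyone. If both
   committed parties defect, the two transfers cancel.

Two protocol branches are genuinely underdetermined by the verbal
definitions and are fixed here as package design choices:

* **Mixed proposer encounters (COMP vs COMS).** Role averaging applies:
  half the time COMP proposes a full-cost deal, which COMS accepts for
  free; half the time COMS proposes a shared-cost deal, which COMP
  accepts (paying ε/2 is no worse than the full cost it was prepared to
  pay). This yields `R − 3ε/4` for COMP and `R − ε/4` for COMS.
* **Compensation flows only to a committed cooperator.** A fake
  committer facing a defaulting partner holds no moral claim in this
  model; with mutual committed defection the transfers cancel exactly.

For the five-strategy model (COMP, C, D, FAKE, FREE) the protocol
reproduces, entry by entry, the closed-form matrix

|      | COMP      | C     | D | FAKE        | FREE  |
|------|-----------|-------|---|-------------|-------|
| COMP | R − ε/2   | R − ε | 0 | S + pδ − ε  | R − ε |
| C    | R         | R     | S | S           | S     |
| D    | 0         | T     | P | P           | P     |
| FAKE | T − pδ    | T     | P | P           | P     |
| FREE | R         | T     | P | P           | P     |

and the test suite asserts equality between the protocol simulator and
this algebra (and its nine-strategy extension) across parameter sets,
including partial enforcement.

## Viability of the proposers

Strategy A is risk-dominant over B — the direction selection favours
for any intensity of selection in large populations — iff
`π_AA + π_AB > π_BA + π_BB`. Substituting the matrix above for the
Donation game (`T = b`, `R = b − c`, `P = 0`, `S = −c`) gives the
viability window of COMP against all of D, FAKE and FREE:

* arrangement cost: `ε < 2(b − c)/3` (binding against FREE), and
* compensation: `δ > c + 3ε/4` (binding against FAKE), scaled by `1/p`
  under partial enforcement.

For the cost-sharing proposer COMS against D, FAKE, FAKS, FREE and
FRES the window widens to `ε < 2(b − c)` and `δ > c + ε/4`: free-riders
must either share the cost or opt out, which removes the asymmetry that
made FREE profitable. `epsilon_boundary()` and `delta_boundary()`
locate these thresholds numerically — bisection on the minimum
risk-dominance margin over the opponent set, tolerance `1e-9`, with a
post-solve certificate that `risk_dominant()` flips across the
boundary — rather than symbolically, so the same code serves the basic,
sharing and costly-punishment models and any `p`. The closed forms
above back the solver in the tests.

## Finite-population dynamics

Evolution is modelled as social learning in a well-mixed population of
size `N`: a focal individual imitates a random model individual with
the Fermi probability `1/(1 + exp(−β Δf))`, where β is the intensity
of selection. Average payoffs exclude self-interaction
(`π_A(k) = ((k−1)π_AA + (N−k)π_AB)/(N−1)`), the standard convention for
imitation dynamics; the one-step probabilities of the embedded
birth–death chain are
`T±(k) = (k/N)((N−k)/N) [1 + exp(∓β(π_A − π_B))]⁻¹`.

**Fixation probabilities.** The closed form
`ρ = [1 + Σ_{i=1}^{N−1} Π_{j=1}^{i} T⁻(j)/T⁺(j)]⁻¹` is evaluated in log
space: the ratio telescopes to `exp(−β Σ_j (π_A(j) − π_B(j)))`, so we
accumulate the inner sums and apply log-sum-exp. This keeps every
probability finite and inside `[0, 1]` for β up to 10 and payoff
spreads of order 10³, where naive products overflow. At `β = 0` the
expression is exactly `1/N`. The independent cross-check in the tests
solves the tridiagonal absorption system of the same chain directly;
the two routes agree to better than `1e-10` over random games within
the stability regime `|β Δπ| ≲ 10` (outside it the *linear solve*, not
the closed form, loses accuracy — its condition number grows
exponentially with the total selection pressure).

**Small-mutation limit.** When mutations are rare the population hops
between monomorphic states, and the dynamics reduce to a `q`-state
Markov chain with off-diagonals `M[i, j] = ρ(j ← i)/(q − 1)`: a mutant
is uniform over the other `q − 1` strategies, and `ρ(j ← i)` is the
fixation probability of a `j`-mutant among `i`-residents. We fix the
index convention by the requirement that the neutral chain (`β = 0`) be
uniform, which it is: every off-diagonal equals `1/(N(q−1))`. The
stationary distribution is the eigenvector of `t(M)` for eigenvalue 1
(dense `eigen()`, adequate for `q ≤ 32`; eigenvalue identified within
`1e-12`, tie-broken by requiring a single-signed eigenvector) with a
constrained least-squares null-space solve as fallback; the result is
accepted only if its residual `‖xM − x‖∞ < 1e-10`, and it is invariant
under strategy reordering.

## The agent-based cross-validation

`simulate_imitation()` is not a fixture generator but the package's
second, independent route to the same quantities: an explicit
asynchronous simulation (one imitation-or-mutation event per step,
matching the ±1 birth–death structure of the analytic chain) with
payoffs recomputed from the live counts at every event — correctness
over speed, which at `N = 100` the Rcpp core affords easily. It uses
R's RNG, so a seed makes runs bit-reproducible. Standard errors of the
time-averaged frequencies come from 20 batch means, because consecutive
states are strongly autocorrelated.

What the simulation emulates is exactly the model: well-mixed pairing,
complete payoff information, uniform mutation. What it does not emulate
is any feature of real social data — assortment, reputation, noise in
perception, repeated interactions — so agreement between simulation and
analytics validates the implementation and the small-mutation
approximation, not the model's empirical adequacy.

Two regimes matter when comparing it to the analytic limit. At
`μ = 10⁻³` and 10⁷ events the time averages match the stationary
distribution within three batch-means standard errors. As μ shrinks the
finite-mutation bias shrinks too, but the estimator needs a horizon
proportional to `1/μ` to see the same number of mutant invasions; the
monotonicity test therefore scales the horizon so that every arm sees
the same expected number of mutations (2·10⁴).

## Study conditions and problem sizes

The defaults are the conditions under which all headline numbers are
quoted: Donation game `b = 2, c = 1` (so `T = 2, R = 1, P = 0,
S = −1`), compensation `δ = 4`, population `N = 100`, selection
`β = 0.1`, full enforcement `p = 1`, and arrangement cost `ε = 0.25` —
a value comfortably inside the viability window `ε < 2/3`, where the
all-COMP state carries the bulk of the stationary mass (0.68). Sweeps
run ε over `[0, 2]` in steps of 0.05 and δ over `[0, 6]` in steps of
0.1. The strategy-space census uses a deduplication grid of
`ε ∈ {0, 0.3, 1.1} × δ ∈ {0, 0.7, 3.1} × p ∈ {0.4, 1}` (payoff rows and
columns rounded to `1e-9`), which collapses the 72 raw trait tuples to
37 behaviourally distinct strategies; every non-catalog one is weakly
dominated by a catalog member at the default conditions. Dominance is
*weak* (never worse, strictly better somewhere) by default — the
verdict the elimination argument needs — with strict dominance
available as an option.

## Known limitations

* One-shot interactions only: no repetition, reputation, apology,
  signalling, or population structure; commitments here are never
  mutually exclusive.
* The analytic path is exact only in the small-mutation limit; for
  non-vanishing mutation rates the agent-based simulator is the tool.
* The costly-punishment comparison uses the standard peer-punishment
  payoff form; variants (per-opponent cost scaling, punishment of
  non-punishers) are out of scope, though the table constructor accepts
  arbitrary entries for sensitivity checks.
* Boundary solving assumes the risk-dominance margin changes sign once
  on the scanned interval, which holds for these piecewise-linear
  margins but is certified post hoc rather than proven.
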