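#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous imitation-with-mutation dynamics in a well-mixed population.
// One event: with probability mu a uniformly chosen individual mutates to a
// uniformly chosen different strategy; otherwise two distinct individuals
// are drawn and the first adopts the second's strategy with the Fermi
// probability computed from their current average payoffs (self-interaction
// excluded). Payoffs are recomputed from the current counts at every event.
// Uses R's RNG, so set.seed() upstream makes runs bit-reproducible.

static inline int sample_strategy(const std::vector<int>& counts, int idx) {
  // map an individual index in [0, N) to its strategy via cumulative counts
  int acc = 0;
  for (size_t s = 0; s < counts.size(); ++s) {
    acc += counts[s];
    if (idx < acc) return (int)s;
  }
  return (int)counts.size() - 1; // unreachable for valid input
}

// [[Rcpp::export]]
List simulate_core(NumericMatrix payoff, IntegerVector init, double beta,
                   double mu, int n_events, int burn_in, int n_batches,
                   int thin) {
  const int q = payoff.nrow();
  std::vector<int> counts(q);
  int N = 0;
  for (int s = 0; s < q; ++s) { counts[s] = init[s]; N += init[s]; }

  NumericMatrix batch_sums(n_batches, q);
  IntegerVector batch_events(n_batches);
  const int kept = n_events - burn_in;
  const int batch_len = kept / n_batches > 0 ? kept / n_batches : 1;

  const int n_snap = n_events / thin + 1;
  IntegerMatrix traj(n_snap, q);
  IntegerVector traj_event(n_snap);
  int snap = 0;
  for (int s = 0; s < q; ++s) traj(snap, s) = counts[s];
  traj_event[snap++] = 0;

  for (int ev = 1; ev <= n_events; ++ev) {
    if (mu > 0.0 && unif_rand() < mu) {
      int ind = (int)(unif_rand() * N);
      int s_old = sample_strategy(counts, ind);
      int s_new = (int)(unif_rand() * (q - 1));
      if (s_new >= s_old) ++s_new;
      --counts[s_old];
      ++counts[s_new];
    } else {
      int i = (int)(unif_rand() * N);
      int j = (int)(unif_rand() * (N - 1));
      if (j >= i) ++j;
      int sf = sample_strategy(counts, i); // focal (imitator)
      int sm = sample_strategy(counts, j); // model (imitated)
      if (sf != sm) {
        double pf = 0.0, pm = 0.0;
        for (int s = 0; s < q; ++s) {
          pf += counts[s] * payoff(sf, s);
          pm += counts[s] * payoff(sm, s);
        }
        pf = (pf - payoff(sf, sf)) / (N - 1);
        pm = (pm - payoff(sm, sm)) / (N - 1);
        double adopt = 1.0 / (1.0 + std::exp(-beta * (pm - pf)));
        if (unif_rand() < adopt) {
          --counts[sf];
          ++counts[sm];
        }
      }
    }
    if (ev > burn_in) {
      int b = (ev - burn_in - 1) / batch_len;
      if (b >= n_batches) b = n_batches - 1;
      for (int s = 0; s < q; ++s) batch_sums(b, s) += counts[s];
      ++batch_events[b];
    }
    if (ev % thin == 0 && snap < n_snap) {
      for (int s = 0; s < q; ++s) traj(snap, s) = counts[s];
      traj_event[snap++] = ev;
    }
  }

  IntegerVector final_counts(q);
  for (int s = 0; s < q; ++s) final_counts[s] = counts[s];
  return List::create(_["batch_sums"] = batch_sums,
                      _["batch_events"] = batch_events,
                      _["trajectory"] = traj,
                      _["trajectory_event"] = traj_event,
                      _["n_snapshots"] = snap,
                      _["final_counts"] = final_counts);
}
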