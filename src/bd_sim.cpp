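#include <Rcpp.h>
using namespace Rcpp;

// Batch of BD runs to absorption on a fixed graph.
//
// ptr/adj: CSR adjacency, 0-based, ptr has n+1 entries.
// dmut:    per-node mutant death rate (k_i/<k>); wild-type rate is 1.
// starts:  0-based initial mutant node, one per run.
//
// Each event: reproducer uniform over all N nodes; victim drawn among the
// reproducer's neighbours with weight equal to its occupant's death rate;
// victim takes the reproducer's label.  Uses R's RNG, so results are
// reproducible from set.seed().
// [[Rcpp::export]]
List bd_ensemble_cpp(IntegerVector ptr, IntegerVector adj, NumericVector dmut,
                     IntegerVector starts, double max_steps) {
  const int N = ptr.size() - 1;
  const int nruns = starts.size();
  std::vector<char> state(N);
  IntegerVector fixed(nruns);
  NumericVector steps(nruns);

  for (int run = 0; run < nruns; ++run) {
    std::fill(state.begin(), state.end(), 0);
    int s0 = starts[run];
    if (s0 < 0 || s0 >= N) stop("start node out of range");
    state[s0] = 1;
    int count = 1;
    double t = 0.0;
    while (count > 0 && count < N) {
      if (t >= max_steps)
        stop("step cap of %.0f BD events exceeded", max_steps);
      int rep = (int)(unif_rand() * N);
      if (rep == N) rep = N - 1;
      double W = 0.0;
      const int e0 = ptr[rep], e1 = ptr[rep + 1];
      for (int e = e0; e < e1; ++e) {
        const int j = adj[e];
        W += state[j] ? dmut[j] : 1.0;
      }
      double u = unif_rand() * W;
      int victim = adj[e1 - 1];
      for (int e = e0; e < e1; ++e) {
        const int j = adj[e];
        u -= state[j] ? dmut[j] : 1.0;
        if (u <= 0.0) { victim = j; break; }
      }
      const char rl = state[rep];
      if (state[victim] != rl) {
        count += rl ? 1 : -1;
        state[victim] = rl;
      }
      t += 1.0;
    }
    fixed[run] = (count == N) ? 1 : 0;
    steps[run] = t;
    if ((run & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed, _["steps"] = steps);
}
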