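#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time SIR over a snapshot sequence.
//
// Status codes: 0 = susceptible, 1 = infectious, 2 = recovered,
// 3 = infected during the current snapshot (infectious from the next one).
//
// Per snapshot t: every node infectious during t attempts, independently
// with probability beta, to infect each currently susceptible neighbor in
// G_t; newly infected nodes start transmitting at snapshot t+1; nodes
// infectious during t recover with probability mu at the end of t. The seed
// is infectious from snapshot 1. The returned value per run is the
// ever-infected count |I u R| after snapshot L (>= 1).
//
// Draws come from R's RNG so set.seed() upstream makes runs reproducible.
// [[Rcpp::export]]
IntegerVector sir_runs_cpp(List snapshots, int n, int source, double beta,
                           double mu, int nruns) {
  int L = snapshots.size();
  std::vector<IntegerMatrix> snaps;
  snaps.reserve(L);
  for (int t = 0; t < L; ++t) snaps.push_back(as<IntegerMatrix>(snapshots[t]));
  if (source < 1 || source > n) stop("source node outside 1..N");

  IntegerVector out(nruns);
  std::vector<unsigned char> status(n);
  for (int run = 0; run < nruns; ++run) {
    std::fill(status.begin(), status.end(), 0);
    status[source - 1] = 1;
    int n_infected = 1;
    int n_active = 1;  // currently infectious
    for (int t = 0; t < L && n_active > 0; ++t) {
      const IntegerMatrix& e = snaps[t];
      int ne = e.nrow();
      int newly = 0;
      for (int i = 0; i < ne; ++i) {
        int u = e(i, 0) - 1, v = e(i, 1) - 1;
        if (status[u] == 1 && status[v] == 0) {
          if (unif_rand() < beta) { status[v] = 3; ++newly; }
        } else if (status[v] == 1 && status[u] == 0) {
          if (unif_rand() < beta) { status[u] = 3; ++newly; }
        }
      }
      // recovery of nodes infectious during t, then promote the newly
      // infected to infectious for t+1
      if (mu > 0.0) {
        for (int i = 0; i < n; ++i) {
          if (status[i] == 1 && unif_rand() < mu) { status[i] = 2; --n_active; }
        }
      }
      if (newly > 0) {
        for (int i = 0; i < n; ++i) {
          if (status[i] == 3) status[i] = 1;
        }
        n_active += newly;
        n_infected += newly;
      }
    }
    out[run] = n_infected;
  }
  return out;
}
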