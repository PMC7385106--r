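#include <Rcpp.h>
using namespace Rcpp;

// Temporal betweenness by foremost-trajectory counting.
//
// A time-respecting trajectory from s starting at snapshot offset t0 is the
// sequence of nodes it occupies at snapshots t0+1, ..., arrival; per
// snapshot it either waits or crosses one edge of that snapshot. For each
// target d the shortest (foremost) trajectories are those first reaching d
// at the minimal arrival snapshot arr(d).
//
// Counting uses one forward dynamic program per source (f[u] = number of
// trajectories occupying u) plus, for every candidate interior node v, the
// same program with v forbidden; the number of shortest s->d trajectories
// passing through v is sigma(d) - sigma_without_v(d). Because arr(d) is the
// earliest time d is ever occupied, no trajectory counted at arr(d) can
// have visited d earlier, so no explicit absorption bookkeeping is needed.
//
// Counts are doubles (they grow multiplicatively with waiting options);
// only ratios enter the betweenness sum.
// [[Rcpp::export]]
NumericVector temporal_betweenness_cpp(List snapshots, int n) {
  int L = snapshots.size();
  std::vector<IntegerMatrix> snaps;
  snaps.reserve(L);
  for (int t = 0; t < L; ++t) snaps.push_back(as<IntegerMatrix>(snapshots[t]));

  NumericVector tb(n);
  std::vector<double> f(n), inflow(n), g(n), gin(n), sigma(n), sig_av(n);
  std::vector<int> arr(n);

  for (int t0 = 0; t0 < L; ++t0) {
    for (int s = 0; s < n; ++s) {
      // forward DP from s at offset t0: arrivals and shortest-path counts
      std::fill(f.begin(), f.end(), 0.0);
      std::fill(sigma.begin(), sigma.end(), 0.0);
      std::fill(arr.begin(), arr.end(), -1);
      f[s] = 1.0;
      int maxarr = -1;
      for (int tau = t0; tau < L; ++tau) {
        const IntegerMatrix& e = snaps[tau];
        int ne = e.nrow();
        std::fill(inflow.begin(), inflow.end(), 0.0);
        for (int i = 0; i < ne; ++i) {
          int u = e(i, 0) - 1, v = e(i, 1) - 1;
          inflow[u] += f[v];
          inflow[v] += f[u];
        }
        for (int d = 0; d < n; ++d) {
          if (d != s && arr[d] < 0 && inflow[d] > 0.0) {
            arr[d] = tau + 1;
            sigma[d] = inflow[d];
            if (tau + 1 > maxarr) maxarr = tau + 1;
          }
          f[d] += inflow[d];
        }
      }
      if (maxarr < 0) continue;  // s reaches no one from this offset

      // interior candidates: nodes reached strictly before the last arrival
      for (int v = 0; v < n; ++v) {
        if (v == s || arr[v] < 0 || arr[v] >= maxarr) continue;
        std::fill(g.begin(), g.end(), 0.0);
        std::fill(sig_av.begin(), sig_av.end(), 0.0);
        g[s] = 1.0;
        for (int tau = t0; tau < maxarr; ++tau) {
          const IntegerMatrix& e = snaps[tau];
          int ne = e.nrow();
          std::fill(gin.begin(), gin.end(), 0.0);
          for (int i = 0; i < ne; ++i) {
            int u = e(i, 0) - 1, w = e(i, 1) - 1;
            gin[u] += g[w];
            gin[w] += g[u];
          }
          for (int d = 0; d < n; ++d) {
            if (arr[d] == tau + 1 && d != s) sig_av[d] = gin[d];
            g[d] += gin[d];
          }
          g[v] = 0.0;  // v is forbidden: trajectories may never occupy it
        }
        double acc = 0.0;
        for (int d = 0; d < n; ++d) {
          if (d == v || d == s || arr[d] < 0) continue;
          if (arr[d] > arr[v])  // d reached after v can pass through v
            acc += (sigma[d] - sig_av[d]) / sigma[d];
        }
        tb[v] += acc;
      }
    }
  }
  return tb;
}
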