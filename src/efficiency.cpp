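#include <Rcpp.h>
using namespace Rcpp;

// Weighted local efficiency: for each node, all-pairs shortest paths
// (Floyd-Warshall) on the subgraph induced on its neighbours, with lengths
// 1 / (w / max(w)) so distances are >= 1 and the efficiency lies in [0, 1].
// Nodes with degree < 2 get 0.
// [[Rcpp::export]]
NumericVector local_efficiency_cpp(NumericMatrix w) {
  const int n = w.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (w(i, j) > mx) mx = w(i, j);
  NumericVector out(n);
  if (mx == 0.0) return out;
  std::vector<int> nb;
  nb.reserve(n);
  std::vector<double> d;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (w(i, j) > 0.0) nb.push_back(j);
    const int k = (int) nb.size();
    if (k < 2) continue;
    d.assign((size_t) k * k, inf);
    for (int a = 0; a < k; ++a) {
      d[a * k + a] = 0.0;
      for (int b = 0; b < k; ++b) {
        const double wab = w(nb[a], nb[b]);
        if (a != b && wab > 0.0) d[a * k + b] = mx / wab;
      }
    }
    for (int m = 0; m < k; ++m)
      for (int a = 0; a < k; ++a) {
        const double dam = d[a * k + m];
        if (dam == inf) continue;
        for (int b = 0; b < k; ++b) {
          const double via = dam + d[m * k + b];
          if (via < d[a * k + b]) d[a * k + b] = via;
        }
      }
    double s = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        if (a != b && d[a * k + b] < inf) s += 1.0 / d[a * k + b];
    out[i] = s / ((double) k * (k - 1));
  }
  return out;
}
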