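#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Jensen-Shannon divergence scan over node histograms.
// Q: n x b matrix, rows strictly positive and summing to 1 (smoothed by the
// caller). Emits the 1-based index pairs (i < j) with JSD(q_i, q_j) < beta.
// Natural logarithm throughout, so the divergence is bounded by log(2).

// [[Rcpp::export]]
IntegerMatrix jsd_edge_scan(NumericMatrix Q, double beta) {
  const int n = Q.nrow();
  const int b = Q.ncol();
  std::vector<int> ei, ej;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < b; ++k) {
        const double qi = Q(i, k);
        const double qj = Q(j, k);
        const double m = 0.5 * (qi + qj);
        d += 0.5 * qi * std::log(qi / m) + 0.5 * qj * std::log(qj / m);
        if (d >= beta) break;
      }
      if (d < beta) {
        ei.push_back(i + 1);
        ej.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t e = 0; e < ei.size(); ++e) {
    out(e, 0) = ei[e];
    out(e, 1) = ej[e];
  }
  return out;
}
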