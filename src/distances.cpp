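#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each cell to any cell of a different
// population. pop is a 1-based integer coding of population labels.
// [[Rcpp::export]]
NumericVector min_cross_dist_cpp(NumericVector x, NumericVector y,
                                 IntegerVector pop) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = x[i], yi = y[i];
    const int pi = pop[i];
    for (int j = 0; j < n; ++j) {
      if (pop[j] == pi) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 1-based rank, within cell i's neighbor list sorted by (distance, tiebreak)
// ascending, of the first neighbor whose population differs from cell i's.
// tiebreak is a permutation rank (1..n) derived from cell_id order.
// Every neighbor preceding the first cross-population one belongs to the
// target's own population, so the rank equals 1 + the number of neighbors
// strictly before it in the (d2, tiebreak) order.
// [[Rcpp::export]]
IntegerVector neighbor_order_cpp(NumericVector x, NumericVector y,
                                 IntegerVector pop, IntegerVector tiebreak) {
  const int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    const int pi = pop[i];
    double best = R_PosInf;
    int best_tb = 0;
    for (int j = 0; j < n; ++j) {
      if (pop[j] == pi) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best || (d2 == best && tiebreak[j] < best_tb)) {
        best = d2;
        best_tb = tiebreak[j];
      }
    }
    int before = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best || (d2 == best && tiebreak[j] < best_tb)) ++before;
    }
    out[i] = before + 1;
  }
  return out;
}
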