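#include <Rcpp.h>
using namespace Rcpp;

// Cumulative DTW alignment cost D(n, n) over the full warping grid.
// Local cost |x_i - y_j| (squared = true gives (x_i - y_j)^2).
// Boundary D(1,1) = d(x_1, y_1); two rolling rows keep memory O(n).
// [[Rcpp::export]]
double dtw_cost(NumericVector x, NumericVector y, bool squared = false) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = x[i] - y[j];
      d = squared ? d * d : std::fabs(d);
      if (i == 0 && j == 0) {
        cur[j] = d;
      } else if (i == 0) {
        cur[j] = d + cur[j - 1];
      } else if (j == 0) {
        cur[j] = d + prev[j];
      } else {
        cur[j] = d + std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      }
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
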