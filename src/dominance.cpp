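#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over value ranks; prefix sums give
// #{inserted values <= v} in O(log n).
struct Fenwick {
  std::vector<int> t;
  explicit Fenwick(int n) : t(n + 1, 0) {}
  void add(int i) { for (; i < (int)t.size(); i += i & -i) t[i]++; }
  int prefix(int i) const { int s = 0; for (; i > 0; i -= i & -i) s += t[i]; return s; }
};

// For each variant i, count n2 = #{j: y_j <= y_i} and
// n12 = #{j: x_j <= x_i and y_j <= y_i}, ties inclusive on both axes.
// This is the direct-counting denominator/numerator of the conditional
// FDR estimator; O(n log n) via a sweep in y with a Fenwick tree over x ranks.
// [[Rcpp::export]]
List dominance_counts(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("dominance_counts: length mismatch");

  // rank x so that rank(v) = #{x_j <= v} among all x (ties share the rank)
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  std::vector<int> xr(n);
  for (int i = 0; i < n; ++i)
    xr[i] = (int)(std::upper_bound(xs.begin(), xs.end(), x[i]) - xs.begin());

  // order by y ascending
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });

  IntegerVector n2(n), n12(n);
  Fenwick bit(n);
  int k = 0;
  while (k < n) {
    int k2 = k; // group of tied y values: insert all, then query all
    while (k2 < n && y[ord[k2]] == y[ord[k]]) ++k2;
    for (int m = k; m < k2; ++m) bit.add(xr[ord[m]]);
    for (int m = k; m < k2; ++m) {
      n2[ord[m]] = k2;
      n12[ord[m]] = bit.prefix(xr[ord[m]]);
    }
    k = k2;
  }
  return List::create(_["n2"] = n2, _["n12"] = n12);
}
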