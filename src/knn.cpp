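#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force k-nearest-neighbour search, returning 1-based indices and
// Euclidean distances. Sizes here stay in the low thousands, where a
// partial-selection scan beats tree construction overhead.
// [[Rcpp::export(name = ".knn_bf")]]
List knn_bf(NumericMatrix ref, NumericMatrix query, int k) {
  const int m = ref.nrow(), n = query.nrow();
  if (m == 0) stop("reference point set is empty");
  if (k < 1) stop("k must be >= 1");
  if (k > m) k = m;
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> rx(m), ry(m), rz(m);
  for (int j = 0; j < m; ++j) { rx[j] = ref(j,0); ry[j] = ref(j,1); rz[j] = ref(j,2); }
  std::vector<std::pair<double,int> > d2(m);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    for (int j = 0; j < m; ++j) {
      const double dx = rx[j]-qx, dy = ry[j]-qy, dz = rz[j]-qz;
      d2[j] = std::make_pair(dx*dx+dy*dy+dz*dz, j);
    }
    std::partial_sort(d2.begin(), d2.begin()+k, d2.end());
    for (int j = 0; j < k; ++j) {
      idx(i,j) = d2[j].second + 1;
      dist(i,j) = std::sqrt(d2[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
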