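#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Neighbour statistics for the Kraskov kNN mutual-information estimator
// (algorithm 1). x and y are N x d marginal sample matrices (d = 3 for
// residue positions). Distances are Euclidean within each marginal and
// the joint-space distance is the max of the two marginal distances.
//
// For each sample i:
//   eps[i] = distance to its k-th nearest neighbour in the joint space
//   nx[i]  = #{ j != i : dx(i,j) < eps[i] }   (strictly within)
//   ny[i]  = #{ j != i : dy(i,j) < eps[i] }
//
// [[Rcpp::export]]
List kraskov_neighbour_stats(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  const int dx = x.ncol();
  const int dy = y.ncol();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N");

  IntegerVector nx(n), ny(n);
  NumericVector eps(n);
  std::vector<double> dmx(n), dmy(n), dj(n), tmp;
  tmp.reserve(n - 1);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double sx = 0.0, sy = 0.0;
      for (int c = 0; c < dx; ++c) {
        const double d = x(i, c) - x(j, c);
        sx += d * d;
      }
      for (int c = 0; c < dy; ++c) {
        const double d = y(i, c) - y(j, c);
        sy += d * d;
      }
      dmx[j] = std::sqrt(sx);
      dmy[j] = std::sqrt(sy);
      dj[j] = std::max(dmx[j], dmy[j]);
    }
    tmp.clear();
    for (int j = 0; j < n; ++j)
      if (j != i) tmp.push_back(dj[j]);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double e = tmp[k - 1];
    eps[i] = e;
    int cx = 0, cy = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dmx[j] < e) ++cx;
      if (dmy[j] < e) ++cy;
    }
    nx[i] = cx;
    ny[i] = cy;
  }

  return List::create(_["eps"] = eps, _["nx"] = nx, _["ny"] = ny);
}
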