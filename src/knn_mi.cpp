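#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) of mutual
// information for one pair of columns. For each point, eps is the
// Chebyshev distance to its k-th nearest neighbour in the joint space;
// nx/ny count marginal neighbours strictly within eps.
static double ksg_pair(const double* x, const double* y, int n, int k) {
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      d[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
NumericMatrix knn_mi_matrix(NumericMatrix X, int k) {
  int n = X.nrow(), p = X.ncol();
  if (k >= n) stop("k_neighbors must be smaller than the sample count");
  NumericMatrix mi(p, p);
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      double v = ksg_pair(&X(0, a), &X(0, b), n, k);
      mi(a, b) = v;
      mi(b, a) = v;
    }
  }
  return mi;
}
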