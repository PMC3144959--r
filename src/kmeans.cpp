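#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lloyd's k-means with squared Euclidean distance on an n x d matrix, from
// the given initial centers. Assignment ties go to the lowest cluster
// index; an empty cluster is re-seeded at the point farthest from its
// assigned centroid. Stops when the assignment reaches a fixed point.
// Returns labels (1-based), centroids, inertia.
// [[Rcpp::export]]
List lloyd_kmeans_cpp(NumericMatrix X, NumericMatrix C0, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), K = C0.nrow();
  NumericMatrix C = clone(C0);
  IntegerVector labels(n, -1);
  std::vector<double> csum(K * d), cnt(K);
  bool changed = true;
  for (int it = 0; it < max_iter && changed; ++it) {
    changed = false;
    std::fill(csum.begin(), csum.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bk = 0;
      for (int k = 0; k < K; ++k) {
        double s = 0;
        for (int j = 0; j < d; ++j) {
          const double diff = X(i, j) - C(k, j);
          s += diff * diff;
        }
        if (s < best) { best = s; bk = k; }
      }
      if (labels[i] != bk + 1) { labels[i] = bk + 1; changed = true; }
      for (int j = 0; j < d; ++j) csum[bk * d + j] += X(i, j);
      cnt[bk] += 1.0;
    }
    if (!changed) break;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0) {
        for (int j = 0; j < d; ++j) C(k, j) = csum[k * d + j] / cnt[k];
      } else {
        // farthest point from its current centroid
        double worst = -1.0;
        int wi = 0;
        for (int i = 0; i < n; ++i) {
          const int a = labels[i] - 1;
          double s = 0;
          for (int j = 0; j < d; ++j) {
            const double diff = X(i, j) - C(a, j);
            s += diff * diff;
          }
          if (s > worst) { worst = s; wi = i; }
        }
        for (int j = 0; j < d; ++j) C(k, j) = X(wi, j);
        changed = true;
      }
    }
  }
  double inertia = 0;
  for (int i = 0; i < n; ++i) {
    const int a = labels[i] - 1;
    double s = 0;
    for (int j = 0; j < d; ++j) {
      const double diff = X(i, j) - C(a, j);
      s += diff * diff;
    }
    inertia += s;
  }
  return List::create(_["labels"] = labels, _["centroids"] = C,
                      _["inertia"] = inertia);
}
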