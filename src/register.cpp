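#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive rigid search: for every (theta, ty, tx) candidate, map the
// moving mask's positive pixels forward (rotate about the image center,
// then translate), round to the nearest pixel, and count hits on the fixed
// mask. Returns the candidate with the highest overlap; ties break toward
// the smallest |tx| + |ty| + |theta_deg|, then toward the earlier candidate.
// [[Rcpp::export]]
NumericVector best_rigid_cpp(NumericVector px, NumericVector py,
                             LogicalMatrix fixed,
                             double cx, double cy,
                             NumericVector txs, NumericVector tys,
                             NumericVector thetas_deg) {
  const int n = px.size();
  const int h = fixed.nrow(), w = fixed.ncol();
  std::vector<double> rx(n), ry(n);
  long best_overlap = -1;
  double best_cost = 0, best_tx = 0, best_ty = 0, best_th = 0;
  for (int it = 0; it < thetas_deg.size(); ++it) {
    const double th = thetas_deg[it] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < n; ++i) {
      const double dx = px[i] - cx, dy = py[i] - cy;
      rx[i] = c * dx - s * dy + cx;
      ry[i] = s * dx + c * dy + cy;
    }
    for (int iy = 0; iy < tys.size(); ++iy) {
      for (int ix = 0; ix < txs.size(); ++ix) {
        long overlap = 0;
        const double tx = txs[ix], ty = tys[iy];
        for (int i = 0; i < n; ++i) {
          const long qx = std::lround(rx[i] + tx);
          const long qy = std::lround(ry[i] + ty);
          if (qx >= 1 && qx <= w && qy >= 1 && qy <= h &&
              fixed(qy - 1, qx - 1)) ++overlap;
        }
        const double cost = std::fabs(tx) + std::fabs(ty) +
                            std::fabs(thetas_deg[it]);
        if (overlap > best_overlap ||
            (overlap == best_overlap && cost < best_cost - 1e-12)) {
          best_overlap = overlap;
          best_cost = cost;
          best_tx = tx; best_ty = ty; best_th = thetas_deg[it];
        }
      }
    }
  }
  return NumericVector::create(best_tx, best_ty, best_th,
                               (double)best_overlap);
}
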