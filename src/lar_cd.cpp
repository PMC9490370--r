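#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the Lagrangian lasso
//   min_b (1/2m)||yc - Xs b||^2 + lambda ||b||_1
// on standardized predictors, with covariance (Gram) updates.
// G = Xs'Xs/m, xy = Xs'yc/m; g = xy - G b is maintained incrementally.
// Stops when the max coefficient change over a full sweep is <= tol or the
// duality gap falls below 1e-8 relative to the null objective.
// [[Rcpp::export(name = ".lar_cd_cpp")]]
NumericVector lar_cd_cpp(const NumericMatrix& G, const NumericVector& xy,
                         const NumericMatrix& Xs, const NumericVector& yc,
                         double lambda, NumericVector b0,
                         double tol, int max_iter) {
  const int p = xy.size();
  const int m = yc.size();
  NumericVector b = clone(b0);
  std::vector<double> g(p);
  for (int j = 0; j < p; ++j) {
    double acc = xy[j];
    for (int l = 0; l < p; ++l) acc -= G(j, l) * b[l];
    g[j] = acc;
  }
  double ynorm2 = 0.0;
  for (int i = 0; i < m; ++i) ynorm2 += yc[i] * yc[i];
  const double gap_scale = std::max(ynorm2 / (2.0 * m), 1e-300);

  for (int iter = 0; iter < max_iter; ++iter) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double bj_old = b[j];
      const double bj_new = soft(g[j] + bj_old, lambda);
      if (bj_new != bj_old) {
        const double d = bj_new - bj_old;
        for (int l = 0; l < p; ++l) g[l] -= G(l, j) * d;
        b[j] = bj_new;
        const double ad = d < 0 ? -d : d;
        if (ad > delta) delta = ad;
      }
    }
    if (delta <= tol) break;
    if ((iter + 1) % 10 == 0) {
      // duality gap from the scaled-residual dual point
      double rss = 0.0, l1 = 0.0;
      std::vector<double> r(m);
      for (int i = 0; i < m; ++i) {
        double acc = yc[i];
        for (int j = 0; j < p; ++j) acc -= Xs(i, j) * b[j];
        r[i] = acc;
        rss += acc * acc;
      }
      for (int j = 0; j < p; ++j) l1 += (b[j] < 0 ? -b[j] : b[j]);
      const double primal = rss / (2.0 * m) + lambda * l1;
      double gmax = 0.0;
      for (int j = 0; j < p; ++j) {
        const double ag = g[j] < 0 ? -g[j] : g[j];
        if (ag > gmax) gmax = ag;
      }
      const double s = (gmax > lambda && gmax > 0.0) ? lambda / gmax : 1.0;
      double dual = 0.0;
      for (int i = 0; i < m; ++i) {
        const double ru = yc[i] - s * r[i];
        dual += yc[i] * yc[i] - ru * ru;
      }
      dual /= 2.0 * m;
      if (primal - dual <= 1e-8 * gap_scale) break;
    }
  }
  return b;
}
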