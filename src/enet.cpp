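#include <Rcpp.h>
using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net
//   (1/2N) sum_i (y_i - phi0 - x_i' phi)^2 + lambda * [(1-gamma)/2 ||phi||^2
//                                                      + gamma ||phi||_1]
// over a decreasing lambda path with warm starts. X and y are used as
// given (no internal standardization); the intercept is handled by
// centering, phi0 = mean(y) - mean(x)' phi.
// [[Rcpp::export(name = ".enet_cd_path")]]
List enet_cd_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                  double gamma, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();

  std::vector<double> xm(p), z(p);
  double ym = mean(y);
  std::vector<double> Xc(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    xm[j] = m;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j) - m;
      Xc[static_cast<size_t>(j) * n + i] = v;
      ss += v * v;
    }
    z[j] = ss / n; // mean square of the centered column
  }

  std::vector<double> r(n), phi(p, 0.0);
  double vary = 0.0;
  for (int i = 0; i < n; ++i) { r[i] = y[i] - ym; vary += r[i] * r[i]; }
  vary = std::max(vary / n, 1e-30);

  NumericMatrix coefs(p, nl);
  NumericVector intercepts(nl);
  IntegerVector iters(nl);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * gamma, l2 = lam * (1.0 - gamma);
    int it = 0;
    for (; it < maxit; ++it) {
      // glmnet-style criterion: stop when no single update changes the
      // objective by more than tol relative to the null variance; robust
      // to weight shuffling between near-collinear columns
      double max_change = 0.0;
      for (int j = 0; j < p; ++j) {
        if (z[j] <= 0.0) continue; // constant column: coefficient stays 0
        const double *xj = &Xc[static_cast<size_t>(j) * n];
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
        rho = rho / n + z[j] * phi[j];
        double newb = soft_threshold(rho, l1) / (z[j] + l2);
        double d = newb - phi[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
          phi[j] = newb;
          double ch = (z[j] + l2) * d * d;
          if (ch > max_change) max_change = ch;
        }
      }
      if (max_change < tol * vary) { ++it; break; }
    }
    iters[l] = it;
    double dot = 0.0;
    for (int j = 0; j < p; ++j) { coefs(j, l) = phi[j]; dot += xm[j] * phi[j]; }
    intercepts[l] = ym - dot;
  }
  return List::create(_["coefficients"] = coefs,
                      _["intercepts"] = intercepts,
                      _["iterations"] = iters);
}
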