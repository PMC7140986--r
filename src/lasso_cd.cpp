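#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for min_a 0.5*||y - D a||^2 + lambda*||a||_1
// (no 1/N factor, no intercept). Residual-update form: r = y - D a is kept
// current so each coordinate step costs O(N). Stops when the largest
// coefficient change in a full sweep drops below tol.
// [[Rcpp::export]]
List lasso_cd(const NumericMatrix& D, const NumericVector& y, double lambda,
              double tol, int max_iter) {
  const int n = D.nrow(), m = D.ncol();
  NumericVector alpha(m);
  NumericVector r = clone(y);
  NumericVector colss(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, j) * D(i, j);
    colss[j] = s;
  }
  int it = 0;
  bool converged = false;
  for (; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < m; ++j) {
      if (colss[j] <= 0.0) continue;  // all-zero column stays at 0
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += D(i, j) * r[i];
      rho += alpha[j] * colss[j];
      double a_new;
      if (rho > lambda) a_new = (rho - lambda) / colss[j];
      else if (rho < -lambda) a_new = (rho + lambda) / colss[j];
      else a_new = 0.0;
      double delta = a_new - alpha[j];
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= delta * D(i, j);
        alpha[j] = a_new;
        double ad = delta < 0 ? -delta : delta;
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) { converged = true; ++it; break; }
  }
  return List::create(_["alpha"] = alpha, _["iterations"] = it,
                      _["converged"] = converged);
}
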