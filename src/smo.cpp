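#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual
//   max  sum(alpha) - 0.5 * alpha' Q alpha,  Q_ij = y_i y_j K_ij
//   s.t. sum(y_i alpha_i) = 0,  0 <= alpha_i <= C,
// with maximal-violating-pair working-set selection. The equality
// constraint is preserved exactly by the pairwise updates; the box
// constraint is enforced by clipping the step.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-6, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n matching y");
  if (max_iter <= 0) max_iter = std::max(20000, 400 * n);

  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // gradient of 0.5 a'Qa - e'a at a = 0

  int iter = 0;
  bool converged = false;
  double gmax = 0.0, gmin = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    gmax = -1e300; gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      const double v = -y[t] * grad[t];
      if (up  && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = (i >= 0 && j >= 0); break; }

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad < 1e-12) quad = 1e-12;
    double step = (gmax - gmin) / quad;  // unconstrained optimal step

    // box caps: alpha_i moves by +y_i*step, alpha_j by -y_j*step
    double cap_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double cap_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    if (step <= 0) break;  // numerically stuck

    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    // keep exactly inside the box against round-off
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    if (alpha[j] < 0) alpha[j] = 0; else if (alpha[j] > C) alpha[j] = C;

    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * step * (K(t, i) - K(t, j));
    }
  }

  // offset b: average -y_t * grad_t over free support vectors, else midpoint
  double bsum = 0.0; int bcnt = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) { bsum += -y[t] * grad[t]; ++bcnt; }
  }
  double b = (bcnt > 0) ? bsum / bcnt : 0.5 * (gmax + gmin);

  // dual objective (maximization form): sum(alpha) - 0.5 a'Qa;
  // grad = Qa - e, so a'Qa = a'(grad + e)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] - 0.5 * alpha[t] * (grad[t] + 1.0);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["objective"] = obj,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
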