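#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimisation for the C-SVC dual with a precomputed
// kernel matrix. Maximal-violating-pair working-set selection; returns the
// dual coefficients and intercept of the decision function
// f(x) = sum_i alpha_i y_i K(x_i, x) + b.
//
// Small-n solver (training sets here are tens to hundreds of points), so the
// full kernel matrix is taken as input and the gradient is kept dense.
// [[Rcpp::export]]
List smo_train(const NumericMatrix& K, const NumericVector& y, double C,
               double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0);
  // u_i = sum_j alpha_j y_j K_ij (decision value without intercept)
  std::vector<double> u(n, 0.0);

  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  while (iter++ < max_iter) {
    // working-set selection: most violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double e = u[t] - y[t];  // E_t
      const bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && -e > m_up) { m_up = -e; i = t; }
      if (in_low && -e < m_low) { m_low = -e; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    const double s = y[i] * y[j];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    if (H - L < 1e-15) continue;
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    const double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double aj = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L; else if (aj > H) aj = H;
    const double ai = alpha[i] + s * (alpha[j] - aj);
    const double di = (ai - alpha[i]) * y[i];
    const double dj = (aj - alpha[j]) * y[j];
    if (std::abs(di) < 1e-15 && std::abs(dj) < 1e-15) break;
    for (int t = 0; t < n; ++t) u[t] += di * K(i, t) + dj * K(j, t);
    alpha[i] = ai;
    alpha[j] = aj;
  }

  // intercept: average over free support vectors, else midpoint of bounds
  double b = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) {
      b += y[t] - u[t];
      ++n_free;
    }
  }
  if (n_free > 0) b /= n_free;
  else b = (m_up + m_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// RBF kernel matrix exp(-gamma * ||x - z||^2) between rows of X and Z.
// [[Rcpp::export]]
NumericMatrix rbf_kernel(const NumericMatrix& X, const NumericMatrix& Z,
                         double gamma) {
  const int n = X.nrow(), m = Z.nrow(), d = X.ncol();
  if (Z.ncol() != d) stop("dimension mismatch");
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - Z(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}
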