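#include <Rcpp.h>
using namespace Rcpp;

// Dual soft-margin SVM solver: sequential minimal optimisation with
// maximal-violating-pair working set selection. Minimises
//   0.5 * a'Qa - e'a,  0 <= a_i <= C,  sum_i a_i y_i = 0,
// where Q_ij = y_i y_j K_ij. The kernel matrix is precomputed in R; n is
// small (tens of samples) throughout this package, so dense O(n) passes per
// iteration are fine.
//
// Convention for the decision function: f(x) = sum_i a_i y_i K(x_i, x) + b.
// For a free support vector t (0 < a_t < C), KKT gives b = y_t - u_t where
// u_t = sum_j a_j y_j K_jt; note -y_t G_t = y_t - u_t, so b averages
// -y_t G_t over free vectors (midpoint of the violation bounds otherwise).
// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const IntegerVector& y,
               double C, double tol = 1e-6, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("length(y) != nrow(K)");
  for (int t = 0; t < n; ++t)
    if (y[t] != 1 && y[t] != -1) stop("labels must be +1/-1");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // G_i = sum_j Q_ij a_j - 1

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && v > m_up)   { m_up = v;  i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    gap = m_up - m_low;
    if (i < 0 || j < 0 || gap < tol) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 1e-12) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 1e-12) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old;
    const double daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * dai * K(i, t) + y[j] * daj * K(j, t));
  }

  double b;
  {
    double up = -R_PosInf, low = R_PosInf, b_free = 0.0;
    int n_free = 0;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { b_free += v; ++n_free; }
      const bool in_up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up  && v > up)  up = v;
      if (in_low && v < low) low = v;
    }
    b = (n_free > 0) ? b_free / n_free : (up + low) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["iterations"] = iter,
                      _["gap"] = gap);
}
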