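#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Nearest-neighbor mutual information between a continuous variable and a
// discrete label (Ross-type estimator):
//   MI = psi(N) - <psi(N_y)> + <psi(k)> - <psi(m_i)>
// where the radius at point i is the distance to its k-th nearest neighbor
// within its own class and m_i counts full-sample points strictly inside
// that radius (the point itself included). Negative estimates are clipped
// at zero by the R wrapper.
static double mi_cd_one(const std::vector<double>& x,
                        const std::vector<int>& y, int k) {
  const int n = (int) x.size();

  // class bookkeeping
  std::vector<int> classes(y);
  std::sort(classes.begin(), classes.end());
  classes.erase(std::unique(classes.begin(), classes.end()), classes.end());

  std::vector<double> radius(n), kused(n), nclass(n);

  // full-sample sorted copy for range counting
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  const double lo0 = xs.front(), hi0 = xs.back();
  if (hi0 - lo0 <= 0) return 0.0;  // constant x

  for (int cls : classes) {
    std::vector<int> idx;
    for (int i = 0; i < n; ++i) if (y[i] == cls) idx.push_back(i);
    const int nc = (int) idx.size();
    const int kk = std::min(k, nc - 1);
    if (kk < 1) return 0.0;
    // order class members by x
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    std::vector<double> xc(nc);
    for (int j = 0; j < nc; ++j) xc[j] = x[idx[j]];
    std::vector<double> cand;
    for (int j = 0; j < nc; ++j) {
      cand.clear();
      const int lo = std::max(0, j - kk), hi = std::min(nc - 1, j + kk);
      for (int t = lo; t <= hi; ++t)
        if (t != j) cand.push_back(std::fabs(xc[t] - xc[j]));
      std::nth_element(cand.begin(), cand.begin() + (kk - 1), cand.end());
      radius[idx[j]] = cand[kk - 1];
      kused[idx[j]] = kk;
      nclass[idx[j]] = nc;
    }
  }

  const double eps = 1e-12;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // strictly-inside count, self included
    const double r = radius[i];
    long m = std::upper_bound(xs.begin(), xs.end(), x[i] + r - eps) -
             std::lower_bound(xs.begin(), xs.end(), x[i] - r + eps);
    if (m < 1) m = 1;
    acc += R::digamma((double) n) - R::digamma(nclass[i]) +
           R::digamma(kused[i]) - R::digamma((double) m);
  }
  return acc / n;
}

// [[Rcpp::export]]
double mi_cd_cpp(const NumericVector& x, const IntegerVector& y, int k) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> yv(y.begin(), y.end());
  return mi_cd_one(xv, yv, k);
}

// Column-wise MI of a matrix against one label vector.
// [[Rcpp::export]]
NumericVector mi_cd_matrix(const NumericMatrix& X, const IntegerVector& y,
                           int k) {
  const int p = X.ncol(), n = X.nrow();
  NumericVector out(p);
  std::vector<int> yv(y.begin(), y.end());
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    out[j] = mi_cd_one(col, yv, k);
  }
  return out;
}
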