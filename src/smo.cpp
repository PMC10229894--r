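#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Soft-margin linear C-SVC solved in the dual by SMO with maximal
// violating pair selection (the libsvm working-set rule). Labels are
// +1/-1; the linear kernel Gram matrix is precomputed (n is small:
// subjects, not voxels). Deterministic: ties in the pair selection are
// broken toward the lowest index.

struct SvmFit {
  std::vector<double> alpha;
  double b;
  int iter;
};

static SvmFit smo_solve(const double* X, int n, int p, const double* y,
                        double C, double tol, int maxiter) {
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X[i + n * k] * X[j + n * k];
      K[i + static_cast<size_t>(n) * j] = s;
      K[j + static_cast<size_t>(n) * i] = s;
    }
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = (Q alpha)_i - 1
  int it = 0;
  double m_up = 0.0, M_low = 0.0;
  for (; it < maxiter; ++it) {
    int i = -1, j = -1;
    m_up = -HUGE_VAL; M_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m_up)   { m_up = v; i = t; }
      if (low && v < M_low) { M_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - M_low < tol) break;
    double s = y[i] * y[j];
    double eta = K[i + static_cast<size_t>(n) * i] +
                 K[j + static_cast<size_t>(n) * j] -
                 2.0 * K[i + static_cast<size_t>(n) * j];
    if (eta <= 0) eta = 1e-12;
    // E_t = f(x_t) - y_t = y_t * G_t
    double delta = (y[i] * G[i] - y[j] * G[j]) / eta;
    double aj_new = alpha[j] + y[j] * delta;
    double L, H;
    if (s < 0) { L = std::max(0.0, alpha[j] - alpha[i]); H = std::min(C, C + alpha[j] - alpha[i]); }
    else       { L = std::max(0.0, alpha[i] + alpha[j] - C); H = std::min(C, alpha[i] + alpha[j]); }
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    double dj = aj_new - alpha[j];
    if (std::fabs(dj) < 1e-14) break;
    double di = -s * dj;
    alpha[i] += di; alpha[j] += dj;
    // snap to the box so round-off never leaves an alpha marginally
    // inside a bound (which would let a stuck pair be reselected)
    if (alpha[i] < 1e-12) alpha[i] = 0.0;
    if (alpha[i] > C - 1e-12) alpha[i] = C;
    if (alpha[j] < 1e-12) alpha[j] = 0.0;
    if (alpha[j] > C - 1e-12) alpha[j] = C;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[t + static_cast<size_t>(n) * i] * di +
                      y[j] * K[t + static_cast<size_t>(n) * j] * dj);
  }
  // bias from the optimality band: free SVs have -y_t G_t = b
  double b;
  double sum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { sum += -y[t] * G[t]; ++nfree; }
  if (nfree > 0) b = sum / nfree; else b = (m_up + M_low) / 2.0;
  SvmFit fit; fit.alpha = alpha; fit.b = b; fit.iter = it;
  return fit;
}

// [[Rcpp::export(name = ".smo_linear_svm")]]
List smo_linear_svm(NumericMatrix X, NumericVector y, double C,
                    double tol = 1e-4, int maxiter = 100000) {
  int n = X.nrow(), p = X.ncol();
  SvmFit fit = smo_solve(X.begin(), n, p, y.begin(), C, tol, maxiter);
  NumericVector w(p);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += fit.alpha[t] * y[t] * X[t + n * k];
    w[k] = s;
  }
  return List::create(_["w"] = w, _["b"] = fit.b,
                      _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["iterations"] = fit.iter);
}

// Leave-one-out CV for the linear SVM with per-fold standardization:
// for each held-out row, feature means/SDs come from the remaining rows
// only, the model is trained on those rows, and the held-out row is
// scored with the same fold parameters. Returns per-row decision values;
// accuracy is decided in R. Zero-SD features get SD 1 (constant within
// the fold), matching the R-level standardize() rule.
// [[Rcpp::export(name = ".smo_loocv_decisions")]]
NumericVector smo_loocv_decisions(NumericMatrix X, NumericVector y, double C,
                                  double tol = 1e-4, int maxiter = 100000) {
  int n = X.nrow(), p = X.ncol();
  NumericVector dec(n);
  std::vector<double> Xtr(static_cast<size_t>(n - 1) * p), ytr(n - 1);
  std::vector<double> mu(p), sd(p);
  for (int hold = 0; hold < n; ++hold) {
    int m = n - 1;
    for (int k = 0; k < p; ++k) {
      double s = 0.0;
      for (int t = 0; t < n; ++t) if (t != hold) s += X[t + n * k];
      mu[k] = s / m;
      double v = 0.0;
      for (int t = 0; t < n; ++t) if (t != hold) {
        double d = X[t + n * k] - mu[k]; v += d * d;
      }
      sd[k] = (m > 1) ? std::sqrt(v / (m - 1)) : 1.0;
      if (sd[k] <= 0) sd[k] = 1.0;
    }
    int r = 0;
    for (int t = 0; t < n; ++t) {
      if (t == hold) continue;
      for (int k = 0; k < p; ++k)
        Xtr[r + static_cast<size_t>(m) * k] = (X[t + n * k] - mu[k]) / sd[k];
      ytr[r] = y[t];
      ++r;
    }
    SvmFit fit = smo_solve(Xtr.data(), m, p, ytr.data(), C, tol, maxiter);
    double f = fit.b;
    for (int k = 0; k < p; ++k) {
      double wk = 0.0;
      for (int t = 0; t < m; ++t)
        wk += fit.alpha[t] * ytr[t] * Xtr[t + static_cast<size_t>(m) * k];
      f += wk * (X[hold + n * k] - mu[k]) / sd[k];
    }
    dec[hold] = f;
  }
  return dec;
}
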