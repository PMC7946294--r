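// L2-regularized L2-loss (squared-hinge) linear support vector
// classification, solved in the primal by a semismooth Newton method with
// Armijo backtracking. The objective is scaled by 1/C,
//   f(w) = ||w||^2 / (2C) + sum_i max(0, 1 - y_i w.x_i)^2,
// which keeps the numbers well-behaved across the whole study penalty grid
// (2^-50 .. 2^50). The ridge term in the Newton system is floored at 1e-10,
// so penalties beyond ~1e10 yield numerically identical (hard-margin)
// solutions. Deterministic: fixed start at w = 0, no randomization, no bias
// term (features are z-scored upstream, so the boundary passes through the
// origin).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// solve (A + jitter I) x = b in place via Cholesky; A is d x d SPD-ish
bool chol_solve(std::vector<double> A, std::vector<double> b, int d,
                double jitter, std::vector<double>& x) {
  for (int i = 0; i < d; ++i) A[i * d + i] += jitter;
  // Cholesky A = L L^T
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0) return false;
    A[j * d + j] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double t = A[i * d + j];
      for (int k = 0; k < j; ++k) t -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = t / A[j * d + j];
    }
  }
  // forward/back substitution
  for (int i = 0; i < d; ++i) {
    double t = b[i];
    for (int k = 0; k < i; ++k) t -= A[i * d + k] * b[k];
    b[i] = t / A[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double t = b[i];
    for (int k = i + 1; k < d; ++k) t -= A[k * d + i] * b[k];
    b[i] = t / A[i * d + i];
  }
  x = b;
  return true;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_svm_l2l2(NumericMatrix x, NumericVector y, double cost,
                           int max_iter = 100, double tol = 1e-12) {
  int n = x.nrow(), d = x.ncol();
  double invC = 1.0 / cost;
  double jitter = std::max(invC, 1e-10);
  std::vector<double> w(d, 0.0), margins(n), g(d), step(d);

  auto objective = [&](const std::vector<double>& wv) {
    double f = 0;
    for (int j = 0; j < d; ++j) f += 0.5 * invC * wv[j] * wv[j];
    for (int i = 0; i < n; ++i) {
      double wx = 0;
      for (int j = 0; j < d; ++j) wx += wv[j] * x(i, j);
      double m = 1.0 - y[i] * wx;
      if (m > 0) f += m * m;
    }
    return f;
  };

  double f = objective(w);
  for (int iter = 0; iter < max_iter; ++iter) {
    // gradient and active set
    for (int j = 0; j < d; ++j) g[j] = invC * w[j];
    std::vector<int> active;
    for (int i = 0; i < n; ++i) {
      double wx = 0;
      for (int j = 0; j < d; ++j) wx += w[j] * x(i, j);
      margins[i] = 1.0 - y[i] * wx;
      if (margins[i] > 0) {
        active.push_back(i);
        for (int j = 0; j < d; ++j) g[j] -= 2.0 * margins[i] * y[i] * x(i, j);
      }
    }
    double gnorm = 0;
    for (int j = 0; j < d; ++j) gnorm += g[j] * g[j];
    if (gnorm < tol * tol * (1.0 + f)) break;
    // generalized Hessian: invC I + 2 Xa^T Xa
    std::vector<double> H(d * d, 0.0);
    for (int idx : active)
      for (int j = 0; j < d; ++j)
        for (int k = 0; k <= j; ++k)
          H[j * d + k] += 2.0 * x(idx, j) * x(idx, k);
    for (int j = 0; j < d; ++j)
      for (int k = j + 1; k < d; ++k) H[j * d + k] = H[k * d + j];
    for (int j = 0; j < d; ++j) H[j * d + j] += invC;
    std::vector<double> rhs(d);
    for (int j = 0; j < d; ++j) rhs[j] = -g[j];
    double jit = jitter;
    while (!chol_solve(H, rhs, d, jit, step)) {
      jit *= 100;
      if (jit > 1e6) stop("svm: Newton system unsolvable");
    }
    double gd = 0;
    for (int j = 0; j < d; ++j) gd += g[j] * step[j];
    if (gd >= 0) break;  // no descent left at numerical precision
    // Armijo backtracking
    double t = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 60; ++ls) {
      std::vector<double> wt(d);
      for (int j = 0; j < d; ++j) wt[j] = w[j] + t * step[j];
      double ft = objective(wt);
      if (ft <= f + 1e-4 * t * gd) {
        w = wt;
        f = ft;
        moved = true;
        break;
      }
      t *= 0.5;
    }
    if (!moved) break;
  }
  return NumericVector(w.begin(), w.end());
}
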