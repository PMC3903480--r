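#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Weighted linear C-SVC solved in the dual by SMO with maximal-violating-pair
// working-set selection. Per-sample box constraints 0 <= alpha_i <= Cw_i carry
// the subclass sample weights into the hinge loss. Linear kernel only; the
// n x n Gram matrix is formed explicitly (n is the training-fold size, small).
//
// min_alpha 1/2 a'Qa - e'a,  Q_ij = y_i y_j x_i'x_j,
// s.t. y'a = 0, 0 <= a_i <= Cw_i.

// [[Rcpp::export(name = ".svm_linear_fit_cpp")]]
List svm_linear_fit_cpp(NumericMatrix X, NumericVector y, NumericVector Cw,
                        double eps = 1e-3, int max_iter = 0) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (Cw.size() != n) stop("length(Cw) must equal nrow(X)");
  for (int i = 0; i < n; ++i)
    if (y[i] != 1.0 && y[i] != -1.0) stop("y must be coded -1/+1");
  if (max_iter <= 0) max_iter = 40000 + 200 * n;

  // Gram matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += X(i, c) * X(j, c);
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double INF = std::numeric_limits<double>::infinity();
  int iter = 0;

  while (iter < max_iter) {
    // select maximal violating pair
    double gmax = -INF, gmin = INF;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double yG = -y[t] * G[t];
      const bool up = (y[t] > 0) ? (alpha[t] < Cw[t]) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < Cw[t]);
      if (up && yG > gmax) { gmax = yG; i = t; }
      if (low && yG < gmin) { gmin = yG; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double Qii = K[(size_t)i * n + i];
    const double Qjj = K[(size_t)j * n + j];
    const double Kij = K[(size_t)i * n + j];
    double quad = Qii + Qjj - 2.0 * Kij;  // ||x_i - x_j||^2
    if (quad <= 0) quad = 1e-12;

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > Cw[i] - Cw[j]) {
        if (alpha[i] > Cw[i]) { alpha[i] = Cw[i]; alpha[j] = Cw[i] - diff; }
      } else {
        if (alpha[j] > Cw[j]) { alpha[j] = Cw[j]; alpha[i] = Cw[j] + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Cw[i]) {
        if (alpha[i] > Cw[i]) { alpha[i] = Cw[i]; alpha[j] = sum - Cw[i]; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > Cw[j]) {
        if (alpha[j] > Cw[j]) { alpha[j] = Cw[j]; alpha[i] = sum - Cw[j]; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double di = y[i] * (alpha[i] - ai_old);
    const double dj = y[j] * (alpha[j] - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K[(size_t)t * n + i] * di + K[(size_t)t * n + j] * dj);
    ++iter;
  }

  // intercept: average over free support vectors, else midpoint of KKT bounds
  double ub = INF, lb = -INF, sum_free = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];  // = w'x_t - y_t
    if (alpha[t] >= Cw[t] - 1e-12 * Cw[t]) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-15) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nfree; sum_free += yG;
    }
  }
  const double b = (nfree > 0) ? -sum_free / nfree : -(ub + lb) / 2.0;

  NumericVector w(d);
  for (int c = 0; c < d; ++c) {
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += alpha[t] * y[t] * X(t, c);
    w[c] = s;
  }

  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
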