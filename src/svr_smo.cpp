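// Epsilon-insensitive support vector regression: RBF kernel helpers and a
// sequential minimal optimization (SMO) solver for the dual, using the
// classic 2n-variable expansion with maximal-violating-pair working-set
// selection.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat sq_dist_cpp(const arma::mat& A, const arma::mat& B) {
  arma::vec an = arma::sum(arma::square(A), 1);
  arma::vec bn = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * A * B.t();
  D.each_col() += an;
  D.each_row() += bn.t();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return D;
}

// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& D2, double gamma) {
  return arma::exp(-gamma * D2);
}

// Solve: min_beta 0.5 beta' K beta - y' beta + eps * sum |beta|
//        s.t. sum beta = 0, -C <= beta_i <= C
// via the 2n-variable box-constrained dual (alpha, alpha*).
// [[Rcpp::export]]
List svr_smo_cpp(const arma::mat& K, const arma::vec& y, double C,
                 double epsilon, double tol = 1e-6, int max_iter = 10000000) {
  const int n = y.n_elem;
  const int l = 2 * n;
  arma::vec alpha(l, arma::fill::zeros);
  arma::vec G(l);
  arma::ivec z(l);
  for (int t = 0; t < l; ++t) {
    if (t < n) { z[t] = 1;  G[t] = epsilon - y[t]; }
    else       { z[t] = -1; G[t] = epsilon + y[t - n]; }
  }
  auto Kq = [&](int s, int t) -> double {
    return z[s] * z[t] * K(s % n, t % n);
  };

  int iter = 0;
  bool converged = false;
  double m_final = 0.0, M_final = 0.0;
  while (iter < max_iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double m = -arma::datum::inf, M = arma::datum::inf;
    for (int t = 0; t < l; ++t) {
      bool in_up  = (z[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool in_low = (z[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -z[t] * G[t];
      if (in_up && v > m) { m = v; i = t; }
      if (in_low && v < M) { M = v; j = t; }
    }
    m_final = m; M_final = M;
    if (i < 0 || j < 0 || m - M < tol) { converged = true; break; }

    double ai_old = alpha[i], aj_old = alpha[j];
    if (z[i] != z[j]) {
      double quad = Kq(i, i) + Kq(j, j) - 2.0 * K(i % n, j % n);
      if (quad <= 0) quad = 1e-12;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kq(i, i) + Kq(j, j) - 2.0 * K(i % n, j % n);
      if (quad <= 0) quad = 1e-12;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double di = alpha[i] - ai_old, dj = alpha[j] - aj_old;
    if (di != 0.0 || dj != 0.0) {
      for (int t = 0; t < l; ++t)
        G[t] += Kq(t, i) * di + Kq(t, j) * dj;
    }
    ++iter;
  }

  arma::vec beta = alpha.head(n) - alpha.tail(n);
  // bias from free dual variables; fall back to the violating-pair midpoint
  double bsum = 0.0; int bcnt = 0;
  for (int t = 0; t < l; ++t) {
    if (alpha[t] > 1e-10 * C && alpha[t] < C * (1.0 - 1e-10)) {
      bsum += -z[t] * G[t];
      ++bcnt;
    }
  }
  double b = bcnt > 0 ? bsum / bcnt : 0.5 * (m_final + M_final);
  double obj = 0.5 * arma::dot(beta, K * beta) - arma::dot(y, beta) +
    epsilon * arma::accu(arma::abs(beta));
  return List::create(_["beta"] = beta, _["b"] = b, _["iter"] = iter,
                      _["converged"] = converged, _["objective"] = obj);
}
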