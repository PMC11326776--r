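#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian step-emission HMM machinery for 2D displacement series.
// Emission model, state k: dx ~ N(mu_k_x, s2_k), dy ~ N(mu_k_y, s2_k),
// axes independent, shared per-axis variance s2_k = 2*D*dt + 2*sigma_loc^2.

static NumericMatrix emission_loglik(const NumericMatrix& steps,
                                     const NumericMatrix& mu,
                                     const NumericVector& s2) {
  const int n = steps.nrow(), K = mu.nrow();
  NumericMatrix B(n, K);
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    double v = s2[k];
    double lc = -l2pi - std::log(v);
    double inv2v = 0.5 / v;
    for (int i = 0; i < n; ++i) {
      double dx = steps(i, 0) - mu(k, 0);
      double dy = steps(i, 1) - mu(k, 1);
      B(i, k) = lc - (dx * dx + dy * dy) * inv2v;
    }
  }
  return B;
}

// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix steps, NumericMatrix mu,
                          NumericVector s2, NumericVector pi0,
                          NumericMatrix A) {
  const int n = steps.nrow(), K = mu.nrow();
  NumericMatrix B = emission_loglik(steps, mu, s2);

  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector cvec(n);
  double loglik = 0.0;

  // scaled forward pass; shift emissions by row max for stability
  std::vector<double> b(K);
  NumericVector rowmax(n);
  for (int i = 0; i < n; ++i) {
    double m = B(i, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, B(i, k));
    rowmax[i] = m;
  }
  for (int k = 0; k < K; ++k)
    alpha(0, k) = pi0[k] * std::exp(B(0, k) - rowmax[0]);
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) c0 += alpha(0, k);
  if (c0 <= 0.0) c0 = 1e-300;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0;
  loglik += std::log(c0) + rowmax[0];

  for (int i = 1; i < n; ++i) {
    double ci = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(i - 1, j) * A(j, k);
      double a = s * std::exp(B(i, k) - rowmax[i]);
      alpha(i, k) = a;
      ci += a;
    }
    if (ci <= 0.0) ci = 1e-300;
    for (int k = 0; k < K; ++k) alpha(i, k) /= ci;
    cvec[i] = ci;
    loglik += std::log(ci) + rowmax[i];
  }

  // scaled backward pass
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int k = 0; k < K; ++k)
      b[k] = beta(i + 1, k) * std::exp(B(i + 1, k) - rowmax[i + 1]);
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += A(j, k) * b[k];
      beta(i, j) = s / cvec[i + 1];
    }
  }

  // posteriors and expected transition counts
  NumericMatrix xi(K, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(i, k) = alpha(i, k) * beta(i, k);
      s += gamma(i, k);
    }
    if (s > 0) for (int k = 0; k < K; ++k) gamma(i, k) /= s;
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int k = 0; k < K; ++k)
      b[k] = std::exp(B(i + 1, k) - rowmax[i + 1]) * beta(i + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(i, j) * A(j, k) * b[k] / cvec[i + 1];
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix steps, NumericMatrix mu,
                          NumericVector s2, NumericVector pi0,
                          NumericMatrix A) {
  const int n = steps.nrow(), K = mu.nrow();
  NumericMatrix B = emission_loglik(steps, mu, s2);
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  const double NEG = -1e300;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : NEG) + B(0, k);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : NEG;

  for (int i = 1; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      double best = delta(i - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(i - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(i, k) = best + B(i, k);
      psi(i, k) = arg;
    }
  }

  IntegerVector path(n);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(n - 1, k) > delta(n - 1, arg)) arg = k;
  path[n - 1] = arg + 1;
  for (int i = n - 2; i >= 0; --i) {
    arg = psi(i + 1, arg);
    path[i] = arg + 1;
  }
  return path;
}
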