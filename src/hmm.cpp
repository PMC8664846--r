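#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dnorm_log(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return -0.9189385332046727 - std::log(sigma) - 0.5 * z * z;
}

// EM (Baum-Welch) for a K-state HMM with Gaussian emissions. Emission SDs
// are either one per state (shared_var = false; the default upstream, since
// intensity noise grows with the number of active fluorophores) or a single
// shared value. The transition matrix gets a sticky Dirichlet prior
// (self_prior mass on the diagonal, prior_strength pseudo-observations per
// row) so short noise excursions do not fragment long dwells. Returns the
// data log-likelihood of the final parameters (used for BIC upstream).
// [[Rcpp::export]]
List hmm_em_cpp(NumericVector y, NumericVector mu0, NumericVector sigma0,
                bool shared_var, double self_prior, double prior_strength,
                int max_iter, double tol, double sigma_floor) {
  int T = y.size(), K = mu0.size();
  NumericVector mu = clone(mu0);
  NumericVector sigma(K);
  for (int k = 0; k < K; ++k)
    sigma[k] = std::max(sigma0[k % sigma0.size()], sigma_floor);
  NumericMatrix A(K, K);
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = 1.0 / K;
  if (K == 1) {
    A(0, 0) = 1.0;
  } else {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        A(i, j) = (i == j) ? self_prior : (1.0 - self_prior) / (K - 1);
  }

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K);
  NumericVector c(T);
  double loglik = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = std::exp(dnorm_log(y[t], mu[k], sigma[k]));

    // scaled forward pass
    double ll = 0.0, s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    if (s <= 0) s = 1e-300;
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    ll += std::log(s);
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        a *= B(t, k);
        alpha(t, k) = a;
        s += a;
      }
      if (s <= 0) s = 1e-300;
      c[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
      ll += std::log(s);
    }

    // scaled backward pass
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        double b = 0.0;
        for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
        beta(t, j) = b / c[t + 1];
      }

    for (int t = 0; t < T; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      if (g > 0)
        for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    NumericMatrix xi(K, K);
    for (int t = 0; t < T - 1; ++t)
      for (int j = 0; j < K; ++j) {
        double aj = alpha(t, j);
        if (aj == 0) continue;
        for (int k = 0; k < K; ++k)
          xi(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }

    // M-step
    NumericVector wsum(K);
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0;
      for (int t = 0; t < T; ++t) { num += gamma(t, k) * y[t]; den += gamma(t, k); }
      wsum[k] = den;
      if (den > 1e-12) mu[k] = num / den;
    }
    if (shared_var) {
      double ss = 0.0;
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < K; ++k) {
          double d = y[t] - mu[k];
          ss += gamma(t, k) * d * d;
        }
      double sg = std::max(std::sqrt(ss / T), sigma_floor);
      for (int k = 0; k < K; ++k) sigma[k] = sg;
    } else {
      for (int k = 0; k < K; ++k) {
        double ss = 0.0;
        for (int t = 0; t < T; ++t) {
          double d = y[t] - mu[k];
          ss += gamma(t, k) * d * d;
        }
        // one pseudo-observation at sigma_floor regularizes near-empty states
        sigma[k] = std::max(std::sqrt((ss + sigma_floor * sigma_floor) /
                                      (wsum[k] + 1.0)), sigma_floor);
      }
    }
    if (K > 1) {
      for (int j = 0; j < K; ++j) {
        double rs = 0.0;
        for (int k = 0; k < K; ++k) {
          double prior = prior_strength *
            ((j == k) ? self_prior : (1.0 - self_prior) / (K - 1));
          xi(j, k) += prior;
          rs += xi(j, k);
        }
        for (int k = 0; k < K; ++k) A(j, k) = xi(j, k) / rs;
      }
    }
    double ps = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = gamma(0, k) + 1e-4; ps += pi[k]; }
    for (int k = 0; k < K; ++k) pi[k] /= ps;

    if (iter > 0 && std::fabs(ll - loglik) < tol * (std::fabs(ll) + 1.0)) {
      loglik = ll;
      break;
    }
    loglik = ll;
  }

  return List::create(_["mu"] = mu, _["sigma"] = sigma, _["A"] = A,
                      _["pi"] = pi, _["loglik"] = loglik);
}

// Viterbi decoding; returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector mu,
                              NumericVector sigma, NumericMatrix A,
                              NumericVector pi) {
  int T = y.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = std::log(std::max(A(j, k), 1e-300));
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(std::max(pi[k], 1e-300)) +
      dnorm_log(y[0], mu[k], sigma[k]);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + dnorm_log(y[t], mu[k], sigma[k]);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
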