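#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM.
// Returns per-frame posteriors (gamma), summed pairwise transition
// posteriors (xi_sum), and the log-likelihood.
// [[Rcpp::export]]
List fb_gaussian(NumericVector x, NumericVector mu, NumericVector sigma,
                 NumericMatrix A, NumericVector pi0) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double s = sigma[k];
      double z = (x[t] - mu[k]) / s;
      double b = std::exp(-0.5 * z * z) / (s * 2.5066282746310002);
      B(t, k) = (b > 1e-300) ? b : 1e-300;
    }
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double ll = 0.0;

  double s0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi0[k] * B(0, k);
    s0 += alpha(0, k);
  }
  c[0] = (s0 > 0) ? s0 : 1e-300;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c[0];
  ll += std::log(c[0]);

  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = acc * B(t, k);
      st += alpha(t, k);
    }
    c[t] = (st > 0) ? st : 1e-300;
    for (int k = 0; k < K; ++k) alpha(t, k) /= c[t];
    ll += std::log(c[t]);
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j)
        acc += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = acc / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      st += gamma(t, k);
    }
    if (st > 0) for (int k = 0; k < K; ++k) gamma(t, k) /= st;
  }

  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double st = 0.0;
    NumericMatrix xi(K, K);
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) /
                   c[t + 1];
        st += xi(j, k);
      }
    }
    if (st > 0) {
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) xi_sum(j, k) += xi(j, k) / st;
    }
  }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = ll);
}

// Most probable state path (Viterbi), 1-based states.
// [[Rcpp::export]]
IntegerVector viterbi_gaussian(NumericVector x, NumericVector mu,
                               NumericVector sigma, NumericMatrix A,
                               NumericVector pi0) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix logB(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double s = sigma[k];
      double z = (x[t] - mu[k]) / s;
      logB(t, k) = -0.5 * z * z - std::log(s) - 0.9189385332046727;
    }
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(std::max(pi0[k], 1e-300)) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(std::max(A(j, k), 1e-300));
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
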