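#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one observation series.
// dens: T x K matrix of state-conditional observation densities (may be
// rescaled by a common per-row factor; the caller corrects the log-likelihood).
// P: K x K row-stochastic transition matrix. delta: initial distribution.
// Returns log-likelihood (up to the caller's rescale), smoothed state
// probabilities gamma (T x K), and expected transition counts xi (K x K,
// summed over t). Entries of P that are exactly zero contribute exactly zero
// to xi, so structural zeros are preserved bit-for-bit by EM.
// [[Rcpp::export]]
List fb_scaled(NumericMatrix dens, NumericMatrix P, NumericVector delta) {
  const int T = dens.nrow(), K = dens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector cvec(T);
  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = delta[k] * dens(0, k);
    c0 += alpha(0, k);
  }
  if (c0 <= 0.0 || !R_finite(c0)) stop("numerical underflow in forward pass at step 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * P(j, k);
      alpha(t, k) = s * dens(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0.0 || !R_finite(ct)) stop("numerical underflow in forward pass at step " + std::to_string(t + 1));
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    cvec[t] = ct;
  }
  // backward (scaled by the same constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += P(j, k) * dens(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / cvec[t + 1];
    }
  }
  // gamma and xi
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); tot += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= tot;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        if (P(j, k) == 0.0) continue;
        xi(j, k) += alpha(t, j) * P(j, k) * dens(t + 1, k) * beta(t + 1, k) / cvec[t + 1];
      }
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Forward pass only; returns the (rescaled) log-likelihood.
// [[Rcpp::export]]
double forward_core(NumericMatrix dens, NumericMatrix P, NumericVector delta) {
  const int T = dens.nrow(), K = dens.ncol();
  std::vector<double> a(K), anew(K);
  double ll = 0.0, c0 = 0.0;
  for (int k = 0; k < K; ++k) { a[k] = delta[k] * dens(0, k); c0 += a[k]; }
  if (c0 <= 0.0 || !R_finite(c0)) stop("numerical underflow in forward pass at step 1");
  for (int k = 0; k < K; ++k) a[k] /= c0;
  ll = std::log(c0);
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += a[j] * P(j, k);
      anew[k] = s * dens(t, k);
      ct += anew[k];
    }
    if (ct <= 0.0 || !R_finite(ct)) stop("numerical underflow in forward pass at step " + std::to_string(t + 1));
    for (int k = 0; k < K; ++k) a[k] = anew[k] / ct;
    ll += std::log(ct);
  }
  return ll;
}

// Viterbi decoding in log space. logdens: T x K log observation densities;
// logP, logdelta: log transition matrix / initial distribution (-Inf encodes
// a forbidden transition, which therefore can never be on the optimal path).
// Ties break toward the lowest state index. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix logdens, NumericMatrix logP, NumericVector logdelta) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix v(T, K);
  IntegerMatrix bp(T, K);
  for (int k = 0; k < K; ++k) v(0, k) = logdelta[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double cand = v(t - 1, j) + logP(j, k);
        if (cand > best) { best = cand; arg = j; }
      }
      v(t, k) = best + logdens(t, k);
      bp(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (v(T - 1, k) > best) { best = v(T - 1, k); arg = k; }
  if (!R_finite(best)) stop("no admissible state path (all paths have zero probability)");
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
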