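#include <Rcpp.h>
using namespace Rcpp;

// Multivariate Bernoulli-emission HMM: scaled forward-backward and
// Baum-Welch over a list of binary observation sequences (bins x marks).
// Emissions are independent Bernoulli per mark given the state.

static inline double emis_prob(const NumericMatrix &E, int s,
                               const IntegerMatrix &obs, int t) {
  double p = 1.0;
  for (int m = 0; m < obs.ncol(); ++m) {
    double e = E(s, m);
    if (e < 1e-6) e = 1e-6;
    if (e > 1.0 - 1e-6) e = 1.0 - 1e-6;
    p *= obs(t, m) ? e : (1.0 - e);
  }
  return p;
}

// Scaled forward-backward for one sequence. Fills gamma (T x S) and
// accumulates transition numerators into xi_acc (S x S); returns loglik.
static double fb_one(const IntegerMatrix &obs, const NumericMatrix &E,
                     const NumericMatrix &A, const NumericVector &pi,
                     NumericMatrix &gamma, NumericMatrix &xi_acc,
                     NumericVector &pi_acc) {
  const int T = obs.nrow(), S = E.nrow();
  NumericMatrix alpha(T, S), beta(T, S), B(T, S);
  NumericVector c(T);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < S; ++s) B(t, s) = emis_prob(E, s, obs, t);
  double tot = 0;
  for (int s = 0; s < S; ++s) { alpha(0, s) = pi[s] * B(0, s); tot += alpha(0, s); }
  if (tot <= 0) tot = 1e-300;
  c[0] = tot;
  for (int s = 0; s < S; ++s) alpha(0, s) /= tot;
  for (int t = 1; t < T; ++t) {
    tot = 0;
    for (int s = 0; s < S; ++s) {
      double a = 0;
      for (int r = 0; r < S; ++r) a += alpha(t - 1, r) * A(r, s);
      alpha(t, s) = a * B(t, s);
      tot += alpha(t, s);
    }
    if (tot <= 0) tot = 1e-300;
    c[t] = tot;
    for (int s = 0; s < S; ++s) alpha(t, s) /= tot;
  }
  for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) {
      double b = 0;
      for (int r = 0; r < S; ++r)
        b += A(s, r) * B(t + 1, r) * beta(t + 1, r);
      beta(t, s) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double g = 0;
    for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); g += gamma(t, s); }
    if (g > 0) for (int s = 0; s < S; ++s) gamma(t, s) /= g;
  }
  for (int t = 0; t + 1 < T; ++t)
    for (int s = 0; s < S; ++s)
      for (int r = 0; r < S; ++r)
        xi_acc(s, r) += alpha(t, s) * A(s, r) * B(t + 1, r) *
                        beta(t + 1, r) / c[t + 1];
  for (int s = 0; s < S; ++s) pi_acc[s] += gamma(0, s);
  double ll = 0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return ll;
}

// [[Rcpp::export]]
List bw_train_cpp(List seqs, NumericMatrix E0, NumericMatrix A0,
                  NumericVector pi0, int max_iter, double tol) {
  NumericMatrix E = clone(E0), A = clone(A0);
  NumericVector pi = clone(pi0);
  const int S = E.nrow(), M = E.ncol(), nseq = seqs.size();
  std::vector<double> llv;
  double prev = R_NegInf;
  for (int it = 0; it < max_iter; ++it) {
    NumericMatrix xi(S, S), e_num(S, M);
    NumericVector pi_acc(S), g_sum(S);
    double ll = 0;
    for (int q = 0; q < nseq; ++q) {
      IntegerMatrix obs = seqs[q];
      NumericMatrix gamma(obs.nrow(), S);
      ll += fb_one(obs, E, A, pi, gamma, xi, pi_acc);
      for (int t = 0; t < obs.nrow(); ++t)
        for (int s = 0; s < S; ++s) {
          g_sum[s] += gamma(t, s);
          for (int m = 0; m < M; ++m)
            if (obs(t, m)) e_num(s, m) += gamma(t, s);
        }
    }
    llv.push_back(ll);
    // M-step
    for (int s = 0; s < S; ++s) {
      double rs = 0;
      for (int r = 0; r < S; ++r) rs += xi(s, r);
      if (rs > 0) for (int r = 0; r < S; ++r) A(s, r) = xi(s, r) / rs;
      if (g_sum[s] > 0)
        for (int m = 0; m < M; ++m) E(s, m) = e_num(s, m) / g_sum[s];
    }
    double ps = 0;
    for (int s = 0; s < S; ++s) ps += pi_acc[s];
    if (ps > 0) for (int s = 0; s < S; ++s) pi[s] = pi_acc[s] / ps;
    if (it > 0 && ll - prev < tol && ll >= prev) { prev = ll; break; }
    prev = ll;
  }
  return List::create(_["emission"] = E, _["transition"] = A,
                      _["initial"] = pi,
                      _["loglik"] = NumericVector(llv.begin(), llv.end()));
}

// Posterior (forward-backward) state probabilities for one sequence.
// [[Rcpp::export]]
List posterior_cpp(IntegerMatrix obs, NumericMatrix E, NumericMatrix A,
                   NumericVector pi) {
  const int S = E.nrow();
  NumericMatrix gamma(obs.nrow(), S), xi(S, S);
  NumericVector pi_acc(S);
  double ll = fb_one(obs, E, A, pi, gamma, xi, pi_acc);
  return List::create(_["posterior"] = gamma, _["loglik"] = ll);
}
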