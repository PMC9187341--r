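#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

namespace {

struct Em2State {
  double mu1, mu2, s1, s2, p1;
  double loglik;
  bool monotone;
  int iter;
};

// One EM chain for a two-component Gaussian mixture with unequal
// variances.  Densities are evaluated directly (two exp, one log per
// point) with a log-sum-exp fallback when both component weights
// underflow.  Variances are floored at `var_floor`.
void run_em2(const NumericVector& x, NumericVector& g, Em2State& st,
             int max_iter, double tol, double var_floor) {
  const int n = x.size();
  const double inv_sqrt2pi = 1.0 / std::sqrt(2.0 * M_PI);
  const double log2pi = std::log(2.0 * M_PI);

  double ll_prev = R_NegInf, ll = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // E step
    ll = 0.0;
    const double c1 = st.p1 * inv_sqrt2pi / st.s1;
    const double c2 = (1.0 - st.p1) * inv_sqrt2pi / st.s2;
    for (int i = 0; i < n; ++i) {
      double z1 = (x[i] - st.mu1) / st.s1, z2 = (x[i] - st.mu2) / st.s2;
      double w1 = c1 * std::exp(-0.5 * z1 * z1);
      double w2 = c2 * std::exp(-0.5 * z2 * z2);
      double den = w1 + w2;
      if (den > DBL_MIN) {
        ll += std::log(den);
        g[i] = w1 / den;
      } else {  // both components underflowed: log-sum-exp
        double a1 = std::log(st.p1) - std::log(st.s1) -
                    0.5 * (log2pi + z1 * z1);
        double a2 = std::log1p(-st.p1) - std::log(st.s2) -
                    0.5 * (log2pi + z2 * z2);
        double m = a1 > a2 ? a1 : a2;
        double lse = m + std::log(std::exp(a1 - m) + std::exp(a2 - m));
        ll += lse;
        g[i] = std::exp(a1 - lse);
      }
    }
    if (it > 0 && ll < ll_prev - 1e-6) st.monotone = false;
    if (it > 0 && ll - ll_prev < tol && ll >= ll_prev - 1e-6) break;
    ll_prev = ll;

    // M step
    double n1 = 0.0, sx1 = 0.0, sx2 = 0.0;
    for (int i = 0; i < n; ++i) {
      n1 += g[i];
      sx1 += g[i] * x[i];
      sx2 += (1.0 - g[i]) * x[i];
    }
    double n2 = n - n1;
    if (n1 < 1e-10) n1 = 1e-10;
    if (n2 < 1e-10) n2 = 1e-10;
    st.mu1 = sx1 / n1;
    st.mu2 = sx2 / n2;
    double v1 = 0.0, v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - st.mu1, d2 = x[i] - st.mu2;
      v1 += g[i] * d1 * d1;
      v2 += (1.0 - g[i]) * d2 * d2;
    }
    st.s1 = std::sqrt(std::max(v1 / n1, var_floor));
    st.s2 = std::sqrt(std::max(v2 / n2, var_floor));
    st.p1 = std::min(std::max(n1 / n, 1e-6), 1.0 - 1e-6);
  }
  st.loglik = ll;
  st.iter += it;
}

}  // namespace

// Two-component Gaussian mixture EM.  Each row of `inits` is one restart:
// (mu1, mu2, sigma1, sigma2, pi1).  All restarts are first run for
// `short_iter` iterations; the one with the highest log-likelihood is then
// continued to convergence (improvement < `tol`) or `max_iter` total
// iterations.  The `monotone` flag records whether the log-likelihood was
// non-decreasing (up to numerical slack) along the selected chain.
// [[Rcpp::export]]
List em_gauss2_cpp(NumericVector x, NumericMatrix inits, int max_iter,
                   double tol, double var_floor, int short_iter = 25) {
  const int n = x.size();
  const double sd_floor = std::sqrt(var_floor);
  NumericVector g(n);

  Em2State best;
  best.loglik = R_NegInf;
  bool have_best = false;

  for (int r = 0; r < inits.nrow(); ++r) {
    Em2State st;
    st.mu1 = inits(r, 0);
    st.mu2 = inits(r, 1);
    st.s1 = std::max(inits(r, 2), sd_floor);
    st.s2 = std::max(inits(r, 3), sd_floor);
    st.p1 = std::min(std::max(inits(r, 4), 1e-6), 1.0 - 1e-6);
    st.monotone = true;
    st.iter = 0;
    run_em2(x, g, st, std::min(short_iter, max_iter), tol, var_floor);
    if (!have_best || st.loglik > best.loglik) {
      best = st;
      have_best = true;
    }
  }
  if (best.iter < max_iter)
    run_em2(x, g, best, max_iter - best.iter, tol, var_floor);
  else {  // refresh responsibilities/loglik at the final parameters
    run_em2(x, g, best, 1, tol, var_floor);
  }

  // order components by mean
  if (best.mu1 > best.mu2) {
    std::swap(best.mu1, best.mu2);
    std::swap(best.s1, best.s2);
    best.p1 = 1.0 - best.p1;
    for (int i = 0; i < n; ++i) g[i] = 1.0 - g[i];
  }

  return List::create(
      _["mu1"] = best.mu1, _["mu2"] = best.mu2, _["sigma1"] = best.s1,
      _["sigma2"] = best.s2, _["pi1"] = best.p1, _["loglik"] = best.loglik,
      _["iter"] = best.iter, _["monotone"] = best.monotone, _["resp1"] = g);
}
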