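// Gibbs samplers for the linear marker-effect models.
//
// Model: y = B b + Z beta + e, e ~ N(0, s2e I).
//  - gibbs_ridge: beta_j ~ N(0, s2b) with a common variance (Bayesian ridge
//    regression; the MCMC route to rrBLUP, and to RKHS when Z is the scaled
//    kernel eigenbasis).
//  - gibbs_bayesb: spike-and-slab; beta_j = 0 with probability pi, otherwise
//    N(0, s2_j) with per-marker scaled-inv-chi^2 variances (scaled-t slab);
//    pi has a Beta prior.
// Fixed effects in B get a flat prior. Variance hyperpriors follow the
// conventional scaled-inverse-chi-squared setup with scales derived from
// var(y) and an a-priori marker R2. All randomness comes from R's RNG, so
// chains are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static double sample_var(const NumericVector& y) {
  double m = mean(y), s = 0.0;
  for (double v : y) s += (v - m) * (v - m);
  return s / (y.size() - 1);
}

static void update_fixed(const NumericMatrix& B, NumericVector& b,
                         NumericVector& e, double s2e) {
  int n = B.nrow();
  for (int k = 0; k < B.ncol(); ++k) {
    double css = 0.0, r = 0.0;
    for (int i = 0; i < n; ++i) { css += B(i,k) * B(i,k); r += B(i,k) * e[i]; }
    if (css <= 0) continue;
    r += css * b[k];
    double bn = R::rnorm(r / css, std::sqrt(s2e / css));
    double d = b[k] - bn;
    for (int i = 0; i < n; ++i) e[i] += B(i,k) * d;
    b[k] = bn;
  }
}

// [[Rcpp::export]]
List gibbs_ridge(NumericMatrix B, NumericMatrix Z, NumericVector y,
                 int n_iter, int burn_in, double df0, double R2) {
  int n = y.size(), p = Z.ncol(), q = B.ncol();
  NumericVector czz(p);
  double msx = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0.0, m = 0.0;
    for (int i = 0; i < n; ++i) { s += Z(i,j) * Z(i,j); m += Z(i,j); }
    czz[j] = s;
    msx += (s - m * m / n) / (n - 1);
  }
  double vy = sample_var(y);
  if (msx <= 0) msx = 1.0;
  double S0e = vy * (1.0 - R2) * (df0 + 2.0) / df0;
  double S0b = vy * R2 / msx * (df0 + 2.0) / df0;

  NumericVector b(q), beta(p), e = clone(y);
  b[0] = mean(y);
  for (int i = 0; i < n; ++i) e[i] -= b[0];
  double s2e = vy * (1.0 - R2), s2b = vy * R2 / msx;

  NumericVector b_m(q), beta_m(p);
  double s2e_m = 0.0, s2b_m = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    update_fixed(B, b, e, s2e);
    double lambda = s2e / s2b, ssb = 0.0;
    for (int j = 0; j < p; ++j) {
      if (czz[j] <= 0) continue;
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += Z(i,j) * e[i];
      r += czz[j] * beta[j];
      double c = czz[j] + lambda;
      double bn = R::rnorm(r / c, std::sqrt(s2e / c));
      double d = beta[j] - bn;
      for (int i = 0; i < n; ++i) e[i] += Z(i,j) * d;
      beta[j] = bn;
      ssb += bn * bn;
    }
    s2b = (df0 * S0b + ssb) / R::rchisq(df0 + p);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (df0 * S0e + sse) / R::rchisq(df0 + n);
    if (it >= burn_in) {
      ++kept;
      for (int k = 0; k < q; ++k) b_m[k] += b[k];
      for (int j = 0; j < p; ++j) beta_m[j] += beta[j];
      s2e_m += s2e; s2b_m += s2b;
    }
  }
  return List::create(_["b"] = b_m / kept, _["beta"] = beta_m / kept,
                      _["s2e"] = s2e_m / kept, _["s2b"] = s2b_m / kept);
}

// [[Rcpp::export]]
List gibbs_bayesb(NumericMatrix B, NumericMatrix Z, NumericVector y,
                  int n_iter, int burn_in, double pi0, double pi_counts,
                  double df0, double R2) {
  int n = y.size(), p = Z.ncol(), q = B.ncol();
  NumericVector czz(p);
  double msx = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0.0, m = 0.0;
    for (int i = 0; i < n; ++i) { s += Z(i,j) * Z(i,j); m += Z(i,j); }
    czz[j] = s;
    msx += (s - m * m / n) / (n - 1);
  }
  double vy = sample_var(y);
  if (msx <= 0) msx = 1.0;
  double S0e = vy * (1.0 - R2) * (df0 + 2.0) / df0;
  // slab scale spreads the marker R2 over the expected nonzero fraction
  double S0b = vy * R2 / (msx * (1.0 - pi0)) * (df0 + 2.0) / df0;

  NumericVector b(q), beta(p), s2j(p, S0b), e = clone(y);
  IntegerVector delta(p, 1);
  b[0] = mean(y);
  for (int i = 0; i < n; ++i) e[i] -= b[0];
  double s2e = vy * (1.0 - R2), pi = pi0;

  NumericVector b_m(q), beta_m(p), incl_m(p);
  double s2e_m = 0.0, pi_m = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    update_fixed(B, b, e, s2e);
    int n_in = 0;
    for (int j = 0; j < p; ++j) {
      if (czz[j] <= 0) { delta[j] = 0; continue; }
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += Z(i,j) * e[i];
      r += czz[j] * beta[j];                     // z_j' (e excluding marker j)
      double v0 = czz[j] * s2e;
      double v1 = v0 + czz[j] * czz[j] * s2j[j];
      double log1 = std::log(1.0 - pi) - 0.5 * (std::log(v1) + r * r / v1);
      double log0 = std::log(pi)       - 0.5 * (std::log(v0) + r * r / v0);
      double p1 = 1.0 / (1.0 + std::exp(log0 - log1));
      int d_new = (R::unif_rand() < p1) ? 1 : 0;
      double bn = 0.0;
      if (d_new == 1) {
        double c = czz[j] + s2e / s2j[j];
        bn = R::rnorm(r / c, std::sqrt(s2e / c));
        ++n_in;
      }
      double d = beta[j] - bn;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] += Z(i,j) * d;
      beta[j] = bn;
      delta[j] = d_new;
      s2j[j] = (d_new == 1)
        ? (df0 * S0b + bn * bn) / R::rchisq(df0 + 1.0)
        : (df0 * S0b) / R::rchisq(df0);
    }
    pi = R::rbeta(pi0 * pi_counts + (p - n_in), (1.0 - pi0) * pi_counts + n_in);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (df0 * S0e + sse) / R::rchisq(df0 + n);
    if (it >= burn_in) {
      ++kept;
      for (int k = 0; k < q; ++k) b_m[k] += b[k];
      for (int j = 0; j < p; ++j) {
        beta_m[j] += beta[j];
        incl_m[j] += delta[j];
      }
      s2e_m += s2e; pi_m += pi;
    }
  }
  return List::create(_["b"] = b_m / kept, _["beta"] = beta_m / kept,
                      _["inclusion"] = incl_m / kept,
                      _["s2e"] = s2e_m / kept, _["pi"] = pi_m / kept);
}
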