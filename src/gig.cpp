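#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Generalized inverse-Gaussian sampler, density
//   f(x) ~ x^{p-1} exp(-(a x + b / x) / 2),  x > 0, a > 0, b >= 0,
// via the uniformly efficient two-sided rejection scheme of Devroye (2014)
// on the log scale. Uses R's RNG so draws are reproducible under set.seed().

static inline double psi_fun(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}

static inline double dpsi_fun(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}

static double gig_draw(double p, double a, double b) {
  if (b < 1e-100) {
    // chi -> 0 limit: plain Gamma(p, rate a/2); requires p > 0
    return R::rgamma(p, 2.0 / a);
  }
  const bool neg = p < 0.0;
  const double lam = std::fabs(p);
  const double omega = std::sqrt(a * b);
  const double swap_scale = std::sqrt(b / a);

  double alpha = std::sqrt(omega * omega + lam * lam) - lam;

  // t > 0 with psi(t) = -1
  double x = -psi_fun(1.0, alpha, lam);
  double t;
  if (x >= 0.5 && x <= 2.0) {
    t = 1.0;
  } else if (x > 2.0) {
    t = std::sqrt(2.0 / (alpha + lam));
  } else {
    t = std::log(4.0 / (alpha + 2.0 * lam));
  }
  // s > 0 with psi(-s) = -1
  x = -psi_fun(-1.0, alpha, lam);
  double s;
  if (x >= 0.5 && x <= 2.0) {
    s = 1.0;
  } else if (x > 2.0) {
    s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  } else {
    double s1 = 1.0 / lam;
    double s2 = std::log(1.0 + 1.0 / alpha +
                         std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (lam > 0.0) ? std::min(s1, s2) : s2;
  }

  const double eta = -psi_fun(t, alpha, lam);
  const double zeta = -dpsi_fun(t, alpha, lam);
  const double theta = -psi_fun(-s, alpha, lam);
  const double xi = dpsi_fun(-s, alpha, lam);
  const double pp = 1.0 / xi;
  const double rr = 1.0 / zeta;
  const double td = t - rr * eta;
  const double sd = s - pp * theta;
  const double q = td + sd;

  double rnd = 0.0;
  for (int guard = 0; guard < 100000; ++guard) {
    const double U = unif_rand();
    const double V = unif_rand();
    const double W = unif_rand();
    if (U < q / (pp + q + rr)) {
      rnd = -sd + q * V;
    } else if (U < (q + rr) / (pp + q + rr)) {
      rnd = td - rr * std::log(V);
    } else {
      rnd = -sd + pp * std::log(V);
    }
    double chi;
    if (rnd > td) {
      chi = std::exp(-eta - zeta * (rnd - t));
    } else if (rnd < -sd) {
      chi = std::exp(-theta + xi * (rnd + s));
    } else {
      chi = 1.0;
    }
    if (W * chi <= std::exp(psi_fun(rnd, alpha, lam))) break;
  }
  double out = std::exp(rnd) *
    (lam / omega + std::sqrt(1.0 + (lam / omega) * (lam / omega)));
  if (neg) out = 1.0 / out;
  return out * swap_scale;
}

// Vectorized GIG draws: parameters recycle to the longest length.
// [[Rcpp::export]]
NumericVector gig_rnd(NumericVector p, NumericVector a, NumericVector b) {
  const int n = std::max(p.size(), std::max(a.size(), b.size()));
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    out[i] = gig_draw(p[i % p.size()], a[i % a.size()], b[i % b.size()]);
  }
  PutRNGstate();
  return out;
}
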