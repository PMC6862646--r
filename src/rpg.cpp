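#include <Rcpp.h>
using namespace Rcpp;

// Exact Polya-Gamma PG(1, z) sampler (Devroye-type alternating series),
// used for data augmentation in the Bernoulli-logit Gibbs sampler.
// All randomness goes through R's RNG so set.seed() governs draws.

static const double TRUNC = 0.64;

// n-th coefficient of the alternating series for the J*(1) density,
// with the left (x <= TRUNC) and right (x > TRUNC) representations.
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC) {
    return M_PI * nph * exp(-nph * nph * M_PI * M_PI * x / 2.0);
  } else {
    return M_PI * nph * pow(2.0 / (M_PI * x), 1.5) *
      exp(-2.0 * nph * nph / x);
  }
}

// CDF of the inverse-Gaussian(mu, lambda = 1) distribution at t,
// written to stay finite as mu -> Inf (the z = 0 limit).
static double pigauss(double t, double mu) {
  double s = 1.0 / sqrt(t);
  double a = s * (t / mu - 1.0);
  double b = -s * (t / mu + 1.0);
  return R::pnorm(a, 0.0, 1.0, 1, 0) +
    exp(2.0 / mu + R::pnorm(b, 0.0, 1.0, 1, 1));
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC].
static double rtigauss(double z) {
  double t = TRUNC;
  z = fabs(z);
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  double x = t + 1.0;
  if (mu > t) {
    // rejection against a truncated inverse-chi-square proposal
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = exp(-0.5 * z * z * x);
    }
  } else {
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1(double zin) {
  double z = 0.5 * fabs(zin);
  double fz = M_PI * M_PI / 8.0 + 0.5 * z * z;
  // mixture weights of the right-exponential and left-IG components
  double p = (M_PI / (2.0 * fz)) * exp(-fz * TRUNC);
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  double q = 2.0 * exp(-z) * pigauss(TRUNC, mu);

  for (;;) {
    double x;
    if (R::unif_rand() < p / (p + q)) {
      x = TRUNC + R::exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze by the alternating partial sums
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = rpg1(z[i]);
  }
  return out;
}
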