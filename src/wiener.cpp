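#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density at the LOWER boundary of a unit-diffusion Wiener
// process on (0, a), starting at w * a (0 < w < 1) with drift v, evaluated at
// decision time t. Series with automatic small-time / large-time regime
// selection; the regime is chosen by comparing the number of terms each
// expansion needs to reach the truncation tolerance eps.
static double wfpt_lower(double t, double a, double w, double v, double eps) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double tau = t / (a * a);

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f;
  if (ks < kl) {                       // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      s += u * std::exp(-u * u / (2.0 * tau));
    }
    f = s / std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {                             // large-time expansion
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    f = s * M_PI;
  }
  if (f < 0.0) f = 0.0;                // truncation can leave tiny negatives

  // back-transform from normalized time and add the drift term
  return f * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

// Defective density at the UPPER (correct) boundary via reflection:
// f_upper(t; a, z, v) = f_lower(t; a, a - z, -v). The diffusion scale s is
// removed by rescaling distances by 1/s and the drift by 1/s; first-passage
// times are unchanged by the spatial rescaling, so no Jacobian appears.
static double wfpt_upper_scaled(double t, double a, double z, double v,
                                double s, double eps) {
  double as = a / s, zs = z / s, vs = v / s;
  return wfpt_lower(t, as, (as - zs) / as, -vs, eps);
}

// Log of the defective first-passage density at the correct (upper) boundary.
// rt are full reaction times; decision time is rt - t_er. The per-trial
// starting-point offset s0 shifts the start from a/2 toward the upper
// boundary (clamped away from both boundaries); kappa scales the drift.
// [[Rcpp::export]]
NumericVector ddm_logpdf_cpp(NumericVector rt, double a, double v, double s,
                             double t_er, NumericVector s0,
                             NumericVector kappa, double eps) {
  int n = rt.size();
  bool rec0 = s0.size() == 1, reck = kappa.size() == 1;
  const double eps_z = 1e-3;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - t_er;
    if (t <= 0.0) { out[i] = R_NegInf; continue; }
    double z = a / 2.0 + (rec0 ? s0[0] : s0[i]);
    if (z < eps_z) z = eps_z;
    if (z > a - eps_z) z = a - eps_z;
    double veff = (reck ? kappa[0] : kappa[i]) * v;
    double f = wfpt_upper_scaled(t, a, z, veff, s, eps);
    out[i] = f > 0.0 ? std::log(f) : R_NegInf;
  }
  return out;
}

// Closed-form absorption probability at the upper boundary.
// [[Rcpp::export]]
double ddm_prob_upper_cpp(double a, double z, double v, double s) {
  double q = 2.0 * v / (s * s);
  if (std::fabs(q * a) < 1e-10) return z / a;
  // stable for both signs of v: divide through by exp(-q z)
  return -std::expm1(-q * z) / -std::expm1(-q * a);
}

// Euler-Maruyama path simulation of the diffusion between boundaries 0 and a,
// start z (possibly per-trial via s0), drift kappa * v, diffusion scale s.
// boundary: 1 = upper (correct), -1 = lower, 0 = censored at tmax.
// [[Rcpp::export]]
List ddm_sample_cpp(int n, double a, double v, double s, double t_er,
                    NumericVector s0, NumericVector kappa, double dt,
                    double tmax) {
  bool rec0 = s0.size() == 1, reck = kappa.size() == 1;
  const double eps_z = 1e-3;
  NumericVector rt(n);
  IntegerVector boundary(n);
  double sqdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double z = a / 2.0 + (rec0 ? s0[0] : s0[i]);
    if (z < eps_z) z = eps_z;
    if (z > a - eps_z) z = a - eps_z;
    double veff = (reck ? kappa[0] : kappa[i]) * v;
    double x = z, t = 0.0;
    int b = 0;
    while (t < tmax) {
      x += veff * dt + s * sqdt * norm_rand();
      t += dt;
      if (x >= a) { b = 1; break; }
      if (x <= 0.0) { b = -1; break; }
    }
    boundary[i] = b;
    rt[i] = b == 0 ? NA_REAL : t + t_er;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}

// Negative log-likelihood kernels used by the inner optimization. Vectors are
// pre-subset to the included trials of a single stimulus class.

// [[Rcpp::export]]
double later_nll_cpp(NumericVector rt, double D, double mu, double sigma,
                     double t_er, NumericVector s0, NumericVector kappa) {
  int n = rt.size();
  bool rec0 = s0.size() == 1, reck = kappa.size() == 1;
  const double eps_D = 1e-3;
  double nll = 0.0;
  double lognorm = R::pnorm(mu / sigma, 0.0, 1.0, 1, 1); // log P(R > 0) at kappa = 1
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - t_er;
    if (t <= 0.0) return R_PosInf;
    double Deff = D - (rec0 ? s0[0] : s0[i]);
    if (Deff < eps_D) Deff = eps_D;
    double mueff = (reck ? kappa[0] : kappa[i]) * mu;
    double kap = reck ? kappa[0] : kappa[i];
    double logZ = (kap == 1.0) ? lognorm : R::pnorm(mueff / sigma, 0.0, 1.0, 1, 1);
    double lp = std::log(Deff) - 2.0 * std::log(t) +
      R::dnorm((Deff / t - mueff) / sigma, 0.0, 1.0, 1) - std::log(sigma) - logZ;
    if (!R_finite(lp)) return R_PosInf;
    nll -= lp;
  }
  return nll;
}

// [[Rcpp::export]]
double ddm_nll_cpp(NumericVector rt, double a, double v, double s,
                   double t_er, NumericVector s0, NumericVector kappa,
                   double eps) {
  NumericVector lp = ddm_logpdf_cpp(rt, a, v, s, t_er, s0, kappa, eps);
  double nll = 0.0;
  for (int i = 0; i < lp.size(); ++i) {
    if (!R_finite(lp[i])) return R_PosInf;
    nll -= lp[i];
  }
  return nll;
}
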