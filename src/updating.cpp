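#include <Rcpp.h>
using namespace Rcpp;

// Rule levels (shared with R/model_space.R):
// 0 no_update, 1 s0_full_memory, 2 s0_decay,
// 3 rate_binary, 4 rate_decay, 5 rate_weighted

static const double EPS_K = 1e-3;   // rate-scaling floor

// Discretized hyperprior over a Bernoulli rate p: uniform grid of N midpoints
// on (0,1), weights initialized from a symmetric Beta(beta0, beta0).
struct BeliefGrid {
  std::vector<double> p, w, w0;
  double alpha;
  void init(int n, double beta0, double alpha_) {
    alpha = alpha_;
    p.resize(n); w.resize(n); w0.resize(n);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      p[i] = (i + 0.5) / n;
      w0[i] = std::pow(p[i], beta0 - 1.0) * std::pow(1.0 - p[i], beta0 - 1.0);
      tot += w0[i];
    }
    for (int i = 0; i < n; ++i) { w0[i] /= tot; w[i] = w0[i]; }
  }
  // forgetting step: mix current posterior with the initial distribution
  void predict() {
    if (alpha == 1.0) return;
    for (size_t i = 0; i < w.size(); ++i)
      w[i] = alpha * w[i] + (1.0 - alpha) * w0[i];
  }
  // Bayes step with a Bernoulli likelihood
  void observe(bool success) {
    double tot = 0.0;
    for (size_t i = 0; i < w.size(); ++i) {
      w[i] *= success ? p[i] : (1.0 - p[i]);
      tot += w[i];
    }
    for (size_t i = 0; i < w.size(); ++i) w[i] /= tot;
  }
  double p_hat() const {
    double e = 0.0;
    for (size_t i = 0; i < w.size(); ++i) e += p[i] * w[i];
    return e;
  }
};

static inline double clamp_k(double k) { return k < EPS_K ? EPS_K : k; }

// Per-trial modulations for one participant's trial sequence.
//
// rdf_uv:   1/2, the trial's true value on the response-defining axis
// tdd_dim:  0 = no target, 1 = color, 2 = orientation
// present:  target presence (drives the TDD-scope uv_applies gating)
//
// Parameter packing per level: s0_full_memory [beta0]; s0_decay [alpha,
// beta0]; rate_binary [kappa0]; rate_decay / rate_weighted [alpha, delta].
//
// Per-trial order: belief forgetting (predictive prior) -> read s0 / kappa
// -> Bayes / rate-step update with the trial's true stimulus values.
// [[Rcpp::export]]
List apply_rules_cpp(IntegerVector rdf_uv, IntegerVector tdd_dim,
                     LogicalVector present,
                     int rdf_level, NumericVector rdf_par,
                     int tdd_level, NumericVector tdd_par,
                     int n_grid) {
  int n = rdf_uv.size();
  NumericVector s0(n), kappa(n);

  // --- RDF scope state ---
  BeliefGrid rdf_belief;
  double rdf_kdecay = 1.0;                 // rate_decay kappa
  double rdf_kw1 = 1.0, rdf_kw2 = 1.0;     // rate_weighted kappas (sum 2)
  int rdf_last = 0;                        // last uv (0 = none yet)
  if (rdf_level == 1) rdf_belief.init(n_grid, rdf_par[0], 1.0);
  if (rdf_level == 2) rdf_belief.init(n_grid, rdf_par[1], rdf_par[0]);

  // --- TDD scope state (per-dimension beliefs for s0 levels) ---
  BeliefGrid tdd_belief[2];
  double tdd_kdecay = 1.0;
  double tdd_kw[2] = {1.0, 1.0};
  int tdd_last = 0;        // last target dimension (0 none); used by decay/weighted,
                           // persists across target-absent trials
  int tdd_prev_trial = 0;  // previous TRIAL's dimension, 0 if it was absent
                           // (rate_binary needs the immediate predecessor)
  if (tdd_level == 1) { tdd_belief[0].init(n_grid, tdd_par[0], 1.0);
                        tdd_belief[1].init(n_grid, tdd_par[0], 1.0); }
  if (tdd_level == 2) { tdd_belief[0].init(n_grid, tdd_par[1], tdd_par[0]);
                        tdd_belief[1].init(n_grid, tdd_par[1], tdd_par[0]); }

  // trajectories for state plots (p_hat or kappa per step; NA when unused)
  NumericMatrix rdf_traj(n, (rdf_level == 5) ? 2 : 1);
  NumericMatrix tdd_traj(n, (tdd_level == 1 || tdd_level == 2 || tdd_level == 5) ? 2 : 1);
  std::fill(rdf_traj.begin(), rdf_traj.end(), NA_REAL);
  std::fill(tdd_traj.begin(), tdd_traj.end(), NA_REAL);

  for (int i = 0; i < n; ++i) {
    double s0_i = 0.0, k_i = 1.0;
    int uv = rdf_uv[i];
    int dim = tdd_dim[i];
    bool pres = present[i];

    // ---------- forgetting (predictive prior) ----------
    if (rdf_level == 1 || rdf_level == 2) rdf_belief.predict();
    if (tdd_level == 1 || tdd_level == 2) { tdd_belief[0].predict(); tdd_belief[1].predict(); }

    // ---------- read modulations ----------
    switch (rdf_level) {
    case 1: case 2: {
      double ph = rdf_belief.p_hat();
      s0_i += (uv == 1) ? std::log(ph / (1.0 - ph)) : std::log((1.0 - ph) / ph);
      rdf_traj(i, 0) = ph;
      break; }
    case 3:
      if (rdf_last != 0 && uv != rdf_last) k_i *= rdf_par[0];
      rdf_traj(i, 0) = (rdf_last != 0 && uv != rdf_last) ? rdf_par[0] : 1.0;
      break;
    case 4:
      k_i *= clamp_k(rdf_kdecay);
      rdf_traj(i, 0) = clamp_k(rdf_kdecay);
      break;
    case 5: {
      double kk = clamp_k(uv == 1 ? rdf_kw1 : rdf_kw2);
      k_i *= kk;
      rdf_traj(i, 0) = clamp_k(rdf_kw1);
      rdf_traj(i, 1) = clamp_k(rdf_kw2);
      break; }
    default: break;
    }

    switch (tdd_level) {
    case 1: case 2: {
      double ph0 = tdd_belief[0].p_hat(), ph1 = tdd_belief[1].p_hat();
      if (pres) {
        double ph = (dim == 1) ? ph0 : ph1;
        s0_i += std::log(ph / (1.0 - ph));
      }
      tdd_traj(i, 0) = ph0; tdd_traj(i, 1) = ph1;
      break; }
    case 3:
      // scaling only on present trials whose immediate predecessor was a
      // present trial with a target in the other dimension
      if (pres && tdd_prev_trial != 0 && dim != tdd_prev_trial) k_i *= tdd_par[0];
      tdd_traj(i, 0) = (pres && tdd_prev_trial != 0 && dim != tdd_prev_trial) ? tdd_par[0] : 1.0;
      break;
    case 4:
      if (pres) k_i *= clamp_k(tdd_kdecay);
      tdd_traj(i, 0) = clamp_k(tdd_kdecay);
      break;
    case 5:
      if (pres) k_i *= clamp_k(tdd_kw[dim - 1]);
      tdd_traj(i, 0) = clamp_k(tdd_kw[0]); tdd_traj(i, 1) = clamp_k(tdd_kw[1]);
      break;
    default: break;
    }

    s0[i] = s0_i;
    kappa[i] = k_i;

    // ---------- update with the trial's true stimulus ----------
    switch (rdf_level) {
    case 1: case 2:
      rdf_belief.observe(uv == 1);
      break;
    case 4: {
      double a = rdf_par[0], d = rdf_par[1];
      double ku = rdf_kdecay;
      if (rdf_last != 0) ku += (uv == rdf_last ? d : -d);
      rdf_kdecay = a * ku + (1.0 - a);
      break; }
    case 5: {
      double a = rdf_par[0], d = rdf_par[1];
      double k1u = rdf_kw1 + (uv == 1 ? d : -d);
      double k2u = rdf_kw2 + (uv == 2 ? d : -d);
      rdf_kw1 = a * k1u + (1.0 - a);
      rdf_kw2 = a * k2u + (1.0 - a);
      break; }
    default: break;
    }
    if (rdf_level == 3) rdf_last = uv;
    else if (rdf_level == 4) rdf_last = uv;

    switch (tdd_level) {
    case 1: case 2:
      tdd_belief[0].observe(pres && dim == 1);
      tdd_belief[1].observe(pres && dim == 2);
      break;
    case 4: {
      double a = tdd_par[0], d = tdd_par[1];
      double ku = tdd_kdecay;
      if (pres && tdd_last != 0) ku += (dim == tdd_last ? d : -d);
      tdd_kdecay = a * ku + (1.0 - a);
      break; }
    case 5: {
      double a = tdd_par[0], d = tdd_par[1];
      double k1u = tdd_kw[0], k2u = tdd_kw[1];
      if (pres) {
        k1u += (dim == 1 ? d : -d);
        k2u += (dim == 2 ? d : -d);
      }
      tdd_kw[0] = a * k1u + (1.0 - a);
      tdd_kw[1] = a * k2u + (1.0 - a);
      break; }
    default: break;
    }
    if (pres) tdd_last = dim;      // persists across absent trials
    tdd_prev_trial = pres ? dim : 0;
  }

  return List::create(_["s0"] = s0, _["kappa"] = kappa,
                      _["rdf_traj"] = rdf_traj, _["tdd_traj"] = tdd_traj);
}
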