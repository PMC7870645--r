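#include <Rcpp.h>
using namespace Rcpp;

// Two-boundary Wiener first-passage-time machinery.
//
// Internal convention: `bsep` is the FULL evidence span between the two
// absorbing boundaries, `w` the relative starting point in (0,1) measured
// from the lower boundary, `drift` points toward the upper boundary, and
// `sigma` is the diffusion noise (evidence / sqrt(s)). The R layer exposes
// the symmetric parameterization (threshold a = bsep / 2) used by the
// closed-form choice-probability and mean-RT expressions.

static const double WFPT_ERR = 1e-9; // per-term truncation tolerance

// Density of the normalized process (unit separation, zero drift, unit
// noise) absorbed at the LOWER boundary at normalized time tt, starting at
// relative position w. Automatic switch between the small-time and
// large-time series based on the number of terms each needs.
static double wfpt_f_norm(double tt, double w) {
  if (tt <= 0.0) return 0.0;
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * WFPT_ERR < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * WFPT_ERR));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * WFPT_ERR < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * WFPT_ERR) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  double p = 0.0;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      p += x * std::exp(-x * x / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// Log defective density of absorption at the LOWER boundary after decision
// time dt (> 0), for drift v toward the upper boundary.
double wfpt_log_lower(double dt, double bsep, double w, double v, double sigma) {
  if (dt <= 0.0) return R_NegInf;
  double ss = bsep / sigma;           // separation of the unit-noise process
  double vv = v / sigma;
  double tt = dt / (ss * ss);         // normalized time
  double f = wfpt_f_norm(tt, w);
  if (f <= 0.0) return R_NegInf;
  return std::log(f) - 2.0 * std::log(ss) - vv * ss * w - vv * vv * dt / 2.0;
}

// Log defective density at either boundary; `upper` selects the boundary.
// Absorption at the upper boundary is the reflection (1 - w, -v).
double wfpt_log(double dt, bool upper, double bsep, double w, double v,
                double sigma) {
  if (upper) return wfpt_log_lower(dt, bsep, 1.0 - w, -v, sigma);
  return wfpt_log_lower(dt, bsep, w, v, sigma);
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector rt, LogicalVector upper,
                               double bsep, double w, double ter,
                               NumericVector drift, double sigma) {
  int n = rt.size();
  if (upper.size() != n) stop("rt and upper must have equal length");
  bool scalar_v = drift.size() == 1;
  if (!scalar_v && drift.size() != n) stop("drift must have length 1 or length(rt)");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = scalar_v ? drift[0] : drift[i];
    out[i] = wfpt_log(rt[i] - ter, upper[i], bsep, w, v, sigma);
  }
  return out;
}

// Euler-Maruyama simulation of the two-boundary diffusion. Returns the
// boundary hit (1 upper, 0 lower, -1 timeout) and the response time
// (non-decision time + first-passage time; NA on timeout). The boundaries
// are shrunk inward by 0.5826 * sigma * sqrt(dt) (Broadie-Glasserman
// continuity correction) so that discrete-time first passages are unbiased
// to leading order in sqrt(dt). Uses R's RNG: seed with set.seed().
// [[Rcpp::export]]
List sim_ddm_cpp(NumericVector drift, double bsep, double w, double ter,
                 double sigma, double dt, double max_time,
                 bool bias_correct = true) {
  if (bsep <= 0.0 || sigma <= 0.0) stop("boundary separation and noise must be positive");
  if (w <= 0.0 || w >= 1.0) stop("relative start must lie in (0,1)");
  if (ter < 0.0) stop("non-decision time must be nonnegative");
  if (dt <= 0.0) stop("time step must be positive");
  if (max_time <= ter) stop("max_time must exceed the non-decision time");
  int n = drift.size();
  double shrink = bias_correct ? 0.5826 * sigma * std::sqrt(dt) : 0.0;
  double up = bsep - shrink, lo = shrink;
  double x0 = w * bsep;
  if (x0 <= lo || x0 >= up) stop("starting point collides with the (corrected) boundaries; reduce dt");
  double sdt = sigma * std::sqrt(dt);
  IntegerVector resp(n);
  NumericVector rt(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = x0, t = 0.0;
    int r = -1;
    while (ter + t <= max_time) {
      x += drift[i] * dt + sdt * norm_rand();
      t += dt;
      if (x >= up) { r = 1; break; }
      if (x <= lo) { r = 0; break; }
    }
    resp[i] = r;
    rt[i] = (r < 0) ? NA_REAL : ter + t;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}
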