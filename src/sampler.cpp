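#include <Rcpp.h>
using namespace Rcpp;

double wfpt_log(double dt, bool upper, double bsep, double w, double v,
                double sigma);

// Hierarchical adaptive Metropolis-within-Gibbs sampler for the four
// built-in models. Subject-level parameters live on the unconstrained
// (raw) scale and are drawn from per-parameter normal group distributions
// N(mu_k, sigma_k). Updates:
//   - subject raws: per-parameter random-walk Metropolis, step sizes
//     adapted toward 0.44 acceptance during warmup;
//   - group means mu_k: conjugate Gibbs under a N(0, prior_mu_sd) prior;
//   - group scales sigma_k: random-walk on log(sigma) with a half-normal
//     prior (plus Jacobian), adapted as above;
//   - model-specific globals (quadratic model's residual sd, on the log
//     scale) with a half-normal prior.
// Model ids: 1 SPDM, 2 DPDM, 3 quadratic RT regression, 4 logistic choice.
// Uses R's RNG throughout (seed via set.seed() before the call).

enum { M_SPDM = 1, M_DPDM = 2, M_QUAD = 3, M_LOGIT = 4 };

static double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct TrialData {
  IntegerVector subj;   // 0-based, sorted by subject
  IntegerVector resp;   // DDM: 1 = right/upper; LOGIT: 1 = chose remembered
  NumericVector rt;     // seconds (DDM)
  NumericVector x;      // V_rem (SPDM/DPDM/QUAD/LOGIT covariate)
  NumericVector s;      // +1 remembered right, -1 remembered left (DDM)
  NumericVector y;      // standardized log RT (QUAD)
  double sigma;         // diffusion noise
  double vavg;          // utility-process reference (DPDM)
  std::vector<int> start, len; // per-subject trial ranges
};

// log-likelihood of one trial given raw subject parameters
static double trial_ll(int model, const TrialData &d, int i,
                       const double *r, double g_lsd) {
  switch (model) {
  case M_SPDM: {
    double a = std::exp(r[0]), w = R::pnorm(r[1], 0, 1, 1, 0),
           t = std::exp(r[2]), dd = std::exp(r[3]), gam = r[4];
    double v = dd * d.s[i] * (d.x[i] - gam);
    return wfpt_log(d.rt[i] - t, d.resp[i] == 1, 2.0 * a, w, v, d.sigma);
  }
  case M_DPDM: {
    double a = std::exp(r[0]), w = R::pnorm(r[1], 0, 1, 1, 0),
           t = std::exp(r[2]), du = std::exp(r[3]), dh = std::exp(r[4]);
    double ldel = R::pnorm(r[5], 0, 1, 1, 1);  // log(delta)
    double l1del = R::pnorm(r[5], 0, 1, 0, 1); // log(1 - delta)
    double vu = du * d.s[i] * (d.x[i] - d.vavg);
    double vh = dh * d.s[i];
    double lu = ldel + wfpt_log(d.rt[i] - t, d.resp[i] == 1, 2.0 * a, w, vu, d.sigma);
    double lh = l1del + wfpt_log(d.rt[i] - t, d.resp[i] == 1, 2.0 * a, w, vh, d.sigma);
    double m = std::max(lu, lh);
    if (!std::isfinite(m)) return R_NegInf;
    return m + std::log(std::exp(lu - m) + std::exp(lh - m));
  }
  case M_QUAD: {
    double e = d.x[i] + r[2];
    double mu = r[0] + r[1] * e * e;
    return R::dnorm(d.y[i], mu, std::exp(g_lsd), 1);
  }
  case M_LOGIT: {
    double lp = r[0] + r[1] * d.x[i];
    return d.resp[i] == 1 ? lp - log1pexp_(lp) : -log1pexp_(lp);
  }
  }
  return R_NegInf;
}

static double subj_ll(int model, const TrialData &d, int s,
                      const double *r, double g_lsd) {
  double ll = 0.0;
  int a = d.start[s], b = a + d.len[s];
  for (int i = a; i < b; ++i) {
    ll += trial_ll(model, d, i, r, g_lsd);
    if (ll == R_NegInf) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
List hier_mwg_cpp(int model, IntegerVector subj, IntegerVector resp,
                  NumericVector rt, NumericVector x, NumericVector s,
                  NumericVector y, int n_subj, double sigma, double vavg,
                  NumericVector prior_mu_sd, NumericVector prior_sigma_sd,
                  int n_chains, int n_iter, int n_warmup, int thin,
                  bool store_loglik) {
  int K = prior_mu_sd.size();
  int n = subj.size();
  if (n_warmup >= n_iter) stop("warmup must be shorter than the chain");
  int n_kept = (n_iter - n_warmup + thin - 1) / thin;
  bool has_glob = (model == M_QUAD);
  int P = 2 * K + (has_glob ? 1 : 0) + K * n_subj;

  TrialData d;
  d.subj = subj; d.resp = resp; d.rt = rt; d.x = x; d.s = s; d.y = y;
  d.sigma = sigma; d.vavg = vavg;
  d.start.assign(n_subj, -1); d.len.assign(n_subj, 0);
  for (int i = 0; i < n; ++i) {
    int ss = subj[i];
    if (ss < 0 || ss >= n_subj) stop("subject index out of range");
    if (d.start[ss] < 0) d.start[ss] = i;
    else if (d.start[ss] + d.len[ss] != i) stop("trials must be sorted by subject");
    d.len[ss]++;
  }
  for (int ss = 0; ss < n_subj; ++ss)
    if (d.len[ss] == 0) stop("every subject needs at least one trial");

  // minimum RT per subject for non-decision-time initialization
  std::vector<double> minrt(n_subj, R_PosInf);
  if (model == M_SPDM || model == M_DPDM)
    for (int i = 0; i < n; ++i)
      minrt[subj[i]] = std::min(minrt[subj[i]], rt[i]);
  int t_idx = (model == M_SPDM || model == M_DPDM) ? 2 : -1;

  NumericVector draws(n_chains * n_kept * P);
  NumericVector loglik(store_loglik ? (R_xlen_t)n_chains * n_kept * n : 0);

  RNGScope scope;
  for (int c = 0; c < n_chains; ++c) {
    // state
    std::vector<double> raw(K * n_subj), mu(K), sg(K, 0.3);
    std::vector<double> leps(K * n_subj, std::log(0.5));
    std::vector<double> leps_sg(K, std::log(0.5));
    std::vector<double> leps_asis(K, std::log(0.3));
    double g_lsd = 0.0, leps_g = std::log(0.3);
    for (int k = 0; k < K; ++k) mu[k] = 0.1 * norm_rand();
    if (t_idx >= 0) {
      double m = 0.0;
      for (int ss = 0; ss < n_subj; ++ss) m += std::log(0.5 * minrt[ss]);
      mu[t_idx] = m / n_subj;
    }
    for (int k = 0; k < K; ++k)
      for (int ss = 0; ss < n_subj; ++ss) {
        double v0 = (k == t_idx) ? std::log(0.5 * minrt[ss])
                                 : mu[k] + 0.1 * norm_rand();
        raw[k * n_subj + ss] = v0;
      }
    if (model == M_QUAD) {
      double v2 = 0.0;
      for (int i = 0; i < n; ++i) v2 += y[i] * y[i];
      g_lsd = 0.5 * std::log(std::max(v2 / n, 1e-6));
    }
    std::vector<double> cur(n_subj), rprop(K);
    for (int ss = 0; ss < n_subj; ++ss) {
      for (int k = 0; k < K; ++k) rprop[k] = raw[k * n_subj + ss];
      cur[ss] = subj_ll(model, d, ss, rprop.data(), g_lsd);
      if (!std::isfinite(cur[ss]))
        stop("non-finite log-likelihood at initialization (subject %d)", ss + 1);
    }

    int kept_i = 0;
    for (int it = 0; it < n_iter; ++it) {
      bool adapting = it < n_warmup;
      double astep = 1.0 / std::sqrt((double)(it + 1));
      // subject-level updates
      for (int ss = 0; ss < n_subj; ++ss) {
        for (int k = 0; k < K; ++k) rprop[k] = raw[k * n_subj + ss];
        for (int k = 0; k < K; ++k) {
          double old = rprop[k];
          double prop = old + std::exp(leps[k * n_subj + ss]) * norm_rand();
          rprop[k] = prop;
          double llp = subj_ll(model, d, ss, rprop.data(), g_lsd);
          double la = llp - cur[ss] +
            R::dnorm(prop, mu[k], sg[k], 1) - R::dnorm(old, mu[k], sg[k], 1);
          double acc = std::isfinite(la) ? std::min(1.0, std::exp(la)) :
                       (la > 0 ? 1.0 : 0.0);
          if (unif_rand() < acc) {
            raw[k * n_subj + ss] = prop;
            cur[ss] = llp;
          } else {
            rprop[k] = old;
          }
          if (adapting) leps[k * n_subj + ss] += astep * (acc - 0.44);
        }
      }
      // group-level updates
      for (int k = 0; k < K; ++k) {
        // conjugate Gibbs for mu_k (prior N(0, prior_mu_sd))
        double sum = 0.0;
        for (int ss = 0; ss < n_subj; ++ss) sum += raw[k * n_subj + ss];
        double prec = n_subj / (sg[k] * sg[k]) +
                      1.0 / (prior_mu_sd[k] * prior_mu_sd[k]);
        double mean = (sum / (sg[k] * sg[k])) / prec;
        mu[k] = mean + norm_rand() / std::sqrt(prec);
        // RW Metropolis on log(sigma_k), half-normal prior
        double lcur = std::log(sg[k]);
        double lprop = lcur + std::exp(leps_sg[k]) * norm_rand();
        double sgp = std::exp(lprop);
        double la = 0.0;
        for (int ss = 0; ss < n_subj; ++ss) {
          double rr = raw[k * n_subj + ss];
          la += R::dnorm(rr, mu[k], sgp, 1) - R::dnorm(rr, mu[k], sg[k], 1);
        }
        double h = prior_sigma_sd[k];
        la += -sgp * sgp / (2 * h * h) + sg[k] * sg[k] / (2 * h * h);
        la += lprop - lcur; // Jacobian of the log transform
        double acc = std::isfinite(la) ? std::min(1.0, std::exp(la)) :
                     (la > 0 ? 1.0 : 0.0);
        if (unif_rand() < acc) sg[k] = sgp;
        if (adapting) leps_sg[k] += astep * (acc - 0.44);
        // interweaved (non-centered) rescaling move: holding the
        // standardized subject effects eta = (raw - mu)/sigma fixed,
        // propose sigma on the log scale and move all raws with it.
        // Breaks the centered scheme's slow mixing when sigma_k is small.
        lcur = std::log(sg[k]);
        lprop = lcur + std::exp(leps_asis[k]) * norm_rand();
        sgp = std::exp(lprop);
        double llnew = 0.0, llold = 0.0;
        std::vector<double> newll(n_subj);
        for (int ss = 0; ss < n_subj && std::isfinite(llnew); ++ss) {
          for (int kk = 0; kk < K; ++kk) rprop[kk] = raw[kk * n_subj + ss];
          double eta = (rprop[k] - mu[k]) / sg[k];
          rprop[k] = mu[k] + sgp * eta;
          newll[ss] = subj_ll(model, d, ss, rprop.data(), g_lsd);
          llnew += newll[ss];
          llold += cur[ss];
        }
        la = llnew - llold - sgp * sgp / (2 * h * h) +
             sg[k] * sg[k] / (2 * h * h) + lprop - lcur;
        acc = std::isfinite(la) ? std::min(1.0, std::exp(la)) :
              (la > 0 ? 1.0 : 0.0);
        if (unif_rand() < acc) {
          for (int ss = 0; ss < n_subj; ++ss) {
            double eta = (raw[k * n_subj + ss] - mu[k]) / sg[k];
            raw[k * n_subj + ss] = mu[k] + sgp * eta;
            cur[ss] = newll[ss];
          }
          sg[k] = sgp;
        }
        if (adapting) leps_asis[k] += astep * (acc - 0.234);
      }
      // global residual scale (quadratic model)
      if (has_glob) {
        double lprop = g_lsd + std::exp(leps_g) * norm_rand();
        double llp = 0.0;
        std::vector<double> newll(n_subj);
        for (int ss = 0; ss < n_subj && std::isfinite(llp); ++ss) {
          for (int k = 0; k < K; ++k) rprop[k] = raw[k * n_subj + ss];
          newll[ss] = subj_ll(model, d, ss, rprop.data(), lprop);
          llp += newll[ss];
        }
        double llc = 0.0;
        for (int ss = 0; ss < n_subj; ++ss) llc += cur[ss];
        double sp = std::exp(lprop), sc = std::exp(g_lsd);
        double la = llp - llc - sp * sp / 2.0 + sc * sc / 2.0 + lprop - g_lsd;
        double acc = std::isfinite(la) ? std::min(1.0, std::exp(la)) :
                     (la > 0 ? 1.0 : 0.0);
        if (unif_rand() < acc) {
          g_lsd = lprop;
          for (int ss = 0; ss < n_subj; ++ss) cur[ss] = newll[ss];
        }
        if (adapting) leps_g += astep * (acc - 0.44);
      }
      // storage
      if (it >= n_warmup && (it - n_warmup) % thin == 0) {
        R_xlen_t base = c + (R_xlen_t)n_chains * kept_i;
        int p = 0;
        for (int k = 0; k < K; ++k) draws[base + (R_xlen_t)n_chains * n_kept * (p++)] = mu[k];
        for (int k = 0; k < K; ++k) draws[base + (R_xlen_t)n_chains * n_kept * (p++)] = sg[k];
        if (has_glob) draws[base + (R_xlen_t)n_chains * n_kept * (p++)] = std::exp(g_lsd);
        for (int k = 0; k < K; ++k)
          for (int ss = 0; ss < n_subj; ++ss)
            draws[base + (R_xlen_t)n_chains * n_kept * (p++)] = raw[k * n_subj + ss];
        if (store_loglik) {
          for (int i = 0; i < n; ++i) {
            int ss = subj[i];
            for (int k = 0; k < K; ++k) rprop[k] = raw[k * n_subj + ss];
            loglik[base + (R_xlen_t)n_chains * n_kept * i] =
              trial_ll(model, d, i, rprop.data(), g_lsd);
          }
        }
        kept_i++;
      }
    }
  }
  draws.attr("dim") = IntegerVector::create(n_chains, n_kept, P);
  List out = List::create(_["draws"] = draws, _["n_kept"] = n_kept);
  if (store_loglik) {
    loglik.attr("dim") = IntegerVector::create(n_chains, n_kept, n);
    out["log_lik"] = loglik;
  }
  return out;
}
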