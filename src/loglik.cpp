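#include <Rcpp.h>
using namespace Rcpp;

// Quadrature marginal log-likelihood of (choice, rating) observations under
// the signal-detection confidence models.
//
// Latent internal samples are marginalized by midpoint quadrature: the
// pre-decision sample over the half-line selected by the action (the
// slope-1000 softmax of the fitting model is treated as a step), the
// post-decision sample over the full line. The subject's confidence uses
// the single low strength in the task without post-decision evidence and
// the agnostic mixture moments of (mu_low, mu_high) when post-decision
// evidence can occur. Ratings enter as continuous values with Gaussian
// report noise (no interval censoring), matching the generative model.
//
// variant: 0 base, 1 temporal weighting (w1 = w_pre, w2 = w_post),
//          2 choice weighting (w1 = w_confirmatory, w2 = w_disconfirmatory),
//          3 choice bias (w1 = w_bias).
// Observations arrive pre-aggregated as unique (d, level, a, r) combos with
// multiplicities in `count`; level: 0 none, 1 low, 2 high.
//
// The report stage is interval-censored: the likelihood of a rating is the
// Gaussian report-noise mass inside the snapped grid cell (cell midpoint
// boundaries at +-0.0625; the outer cells absorb the clipped tails), which
// matches the clip-and-snap report stage of the generative model and stays
// well-posed as sigma_report -> 0.

static inline double dnorm0(double z) {
  return 0.3989422804014327 * std::exp(-0.5 * z * z);
}

static inline double pnorm0(double z) {
  return 0.5 * std::erfc(-z * 0.7071067811865475);
}

// probability that a noisy report around conf lands in the cell of rating r
static inline double cell_mass(double r, double conf, double inv_sig) {
  const double half = 0.0625;
  double hi = (r > 1.0 - 1e-9) ? 1.0
              : pnorm0((r + half - conf) * inv_sig);
  double lo = (r < 1e-9) ? 0.0
              : pnorm0((r - half - conf) * inv_sig);
  return hi - lo;
}

static inline double clamp_conf(double p) {
  const double eps = 1e-6;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

static inline double logistic(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
double cpp_loglik(IntegerVector d, IntegerVector level, IntegerVector a,
                  NumericVector r, NumericVector count,
                  double m, double mu_low, double mu_high,
                  double sigma_report, int variant, double w1, double w2,
                  int n_pre, int n_post) {
  const int nobs = d.size();
  const double span = 8.0;
  const double mu1 = mu_low, s21 = 1.0;
  const double mu2 = 0.5 * (mu_low + mu_high);
  const double half = 0.5 * (mu_high - mu_low);
  const double s22 = half * half + 1.0;
  const double lobias = (variant == 3) ? std::log(w1 / (1.0 - w1)) : 0.0;

  // pre-decision grids per action (index 0: a=-1, 1: a=+1)
  std::vector<std::vector<double>> xpre(2);
  double hpre[2];
  for (int ai = 0; ai < 2; ++ai) {
    double aa = (ai == 0) ? -1.0 : 1.0;
    double lo = -mu_low - span, hi = mu_low + span;
    if (aa > 0) lo = std::max(lo, m); else hi = std::min(hi, m);
    if (hi <= lo) { hpre[ai] = 0.0; xpre[ai].assign(n_pre, m); continue; }
    double h = (hi - lo) / n_pre;
    hpre[ai] = h;
    xpre[ai].resize(n_pre);
    for (int i = 0; i < n_pre; ++i) xpre[ai][i] = lo + (i + 0.5) * h;
  }
  // post-decision grid (full line around the widest strength)
  double plo = -mu_high - span, phi_ = mu_high + span;
  double hpost = (phi_ - plo) / n_post;
  std::vector<double> xpost(n_post);
  for (int j = 0; j < n_post; ++j) xpost[j] = plo + (j + 0.5) * hpost;

  // confidence grids
  std::vector<std::vector<double>> conf1(2);          // [a][i]
  std::vector<std::vector<double>> conf2(2);          // [a][i * n_post + j]
  for (int ai = 0; ai < 2; ++ai) {
    double aa = (ai == 0) ? -1.0 : 1.0;
    conf1[ai].resize(n_pre);
    for (int i = 0; i < n_pre; ++i) {
      double lop = 2.0 * mu1 * xpre[ai][i] / s21;   // direction log-odds
      double lt;
      switch (variant) {
        case 1: lt = w1 * aa * lop; break;
        case 3: lt = aa * lop + lobias; break;
        default: lt = aa * lop;
      }
      conf1[ai][i] = clamp_conf(logistic(lt));
    }
    conf2[ai].resize((size_t)n_pre * n_post);
    for (int i = 0; i < n_pre; ++i) {
      double lop = 2.0 * mu2 * xpre[ai][i] / s22;
      for (int j = 0; j < n_post; ++j) {
        double loq = 2.0 * mu2 * xpost[j] / s22;
        double lt;
        switch (variant) {
          case 1: lt = w1 * aa * lop + w2 * aa * loq; break;
          case 2: {
            double w = (xpost[j] * aa > 0) ? w1 : w2;
            lt = aa * lop + w * aa * loq; break;
          }
          case 3: lt = aa * (lop + loq) + lobias; break;
          default: lt = aa * (lop + loq);
        }
        conf2[ai][(size_t)i * n_post + j] = clamp_conf(logistic(lt));
      }
    }
  }

  // density weights: pre per (d, a); post per (d, strength level)
  std::vector<std::vector<double>> wpre(4), wpost(4);
  for (int di = 0; di < 2; ++di) {
    double dd = (di == 0) ? -1.0 : 1.0;
    for (int ai = 0; ai < 2; ++ai) {
      std::vector<double>& w = wpre[di * 2 + ai];
      w.resize(n_pre);
      for (int i = 0; i < n_pre; ++i)
        w[i] = dnorm0(xpre[ai][i] - dd * mu_low) * hpre[ai];
    }
    for (int li = 0; li < 2; ++li) {
      double th = (li == 0) ? mu_low : mu_high;
      std::vector<double>& w = wpost[di * 2 + li];
      w.resize(n_post);
      for (int j = 0; j < n_post; ++j)
        w[j] = dnorm0(xpost[j] - dd * th) * hpost;
    }
  }

  const double inv_sig = 1.0 / sigma_report;
  // support cutoffs: interior cells vanish beyond the cell half-width plus
  // 8 noise SDs; the outer cells are one-sided
  const double cut = 0.0625 + 8.0 * sigma_report;
  double ll = 0.0;
  // cache of rating kernels per (a, r) for the 2-D case, with per-row
  // nonzero column ranges (confidence is monotone-ish in x_post, so the
  // support of each row is an interval)
  std::vector<double> kern((size_t)n_pre * n_post);
  std::vector<int> rowlo(n_pre), rowhi(n_pre);
  int cached_ai = -1;
  double cached_r = -99.0;
  for (int o = 0; o < nobs; ++o) {
    int ai = (a[o] > 0) ? 1 : 0;
    int di = (d[o] > 0) ? 1 : 0;
    double ro = r[o];
    double p;
    const bool top = ro > 1.0 - 1e-9, bot = ro < 1e-9;
    if (level[o] == 0) {
      const std::vector<double>& cf = conf1[ai];
      const std::vector<double>& w = wpre[di * 2 + ai];
      double s = 0.0;
      for (int i = 0; i < n_pre; ++i) {
        double dd2 = ro - cf[i];
        if (!top && dd2 < -cut) continue;
        if (!bot && dd2 > cut) continue;
        s += w[i] * cell_mass(ro, cf[i], inv_sig);
      }
      p = s;
    } else {
      if (ai != cached_ai || ro != cached_r) {
        const std::vector<double>& cf = conf2[ai];
        for (int i = 0; i < n_pre; ++i) {
          double* krow = &kern[(size_t)i * n_post];
          const double* crow = &cf[(size_t)i * n_post];
          int lo = n_post, hi = -1;
          for (int j = 0; j < n_post; ++j) {
            double dd2 = ro - crow[j];
            if ((!top && dd2 < -cut) || (!bot && dd2 > cut)) {
              krow[j] = 0.0; continue;
            }
            krow[j] = cell_mass(ro, crow[j], inv_sig);
            if (j < lo) lo = j;
            hi = j;
          }
          rowlo[i] = lo; rowhi[i] = hi;
        }
        cached_ai = ai; cached_r = ro;
      }
      const std::vector<double>& wp = wpre[di * 2 + ai];
      const std::vector<double>& wq = wpost[di * 2 + (level[o] - 1)];
      double s = 0.0;
      for (int i = 0; i < n_pre; ++i) {
        if (rowhi[i] < rowlo[i]) continue;
        double t = 0.0;
        const double* krow = &kern[(size_t)i * n_post];
        for (int j = rowlo[i]; j <= rowhi[i]; ++j) t += krow[j] * wq[j];
        s += wp[i] * t;
      }
      p = s;
    }
    ll += count[o] * std::log(std::max(p, 1e-300));
  }
  return ll;
}
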