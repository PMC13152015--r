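#include <Rcpp.h>
#include "ct_model.h"
using namespace Rcpp;

typedef std::complex<double> cplx;

namespace {

// frequency-dependent complex factors of the loop transfer, independent of
// the gains; precomputed once per chain when the rates and delay are fixed
struct Grid {
  std::vector<cplx> L1, L2, L2E, L3E, W;
  void build(const std::vector<double>& freqs, double alpha, double beta,
             double gamma_e, double t0) {
    const cplx I(0.0, 1.0);
    const size_t n = freqs.size();
    L1.resize(n); L2.resize(n); L2E.resize(n); L3E.resize(n); W.resize(n);
    for (size_t j = 0; j < n; ++j) {
      const double w = 2.0 * M_PI * freqs[j];
      const cplx L = 1.0 / ((1.0 - I * w / alpha) * (1.0 - I * w / beta));
      const cplx E2 = std::exp(I * w * t0);
      L1[j] = L; L2[j] = L * L; L2E[j] = L * L * E2; L3E[j] = L * L * L * E2;
      W[j] = (1.0 - I * w / gamma_e) * (1.0 - I * w / gamma_e);
    }
  }
  // dispersion ratio f = q^2 r_e^2 / wave at grid point j
  inline cplx dispersion(size_t j, const double* g) const {
    const cplx den_srs = 1.0 - L2[j] * g[4];
    const cplx den_ei = 1.0 - L1[j] * g[1];
    return 1.0 - ((L1[j] * g[0] + (L2E[j] * g[2] + L3E[j] * g[3]) / den_srs)
                  / den_ei) / W[j];
  }
  // un-normalized power at grid point j; den_mod = smallest denominator
  inline double power(size_t j, const double* g, double* den_mod) const {
    const cplx den_srs = 1.0 - L2[j] * g[4];
    const cplx den_ei = 1.0 - L1[j] * g[1];
    const cplx q2 = W[j] -
      (L1[j] * g[0] + (L2E[j] * g[2] + L3E[j] * g[3]) / den_srs) / den_ei;
    double m = std::abs(q2);
    if (std::abs(den_srs) < m) m = std::abs(den_srs);
    if (std::abs(den_ei) < m) m = std::abs(den_ei);
    *den_mod = m;
    return std::norm(L2[j]) /
      (std::norm(den_srs) * std::norm(den_ei) * std::norm(q2));
  }
};

inline double dc_loop(const double* g) {
  return 1.0 - g[0] / (1.0 - g[1]) -
    (g[2] + g[3]) / ((1.0 - g[4]) * (1.0 - g[1]));
}

inline int winding_pre(const Grid& grid, const double* g) {
  const double dc = dc_loop(g);
  double total = 0.0;
  double prev_arg = (dc >= 0.0) ? 0.0 : M_PI;
  for (size_t j = 0; j < grid.L1.size(); ++j) {
    const double a = std::arg(grid.dispersion(j, g));
    double d = a - prev_arg;
    while (d > M_PI) d -= 2.0 * M_PI;
    while (d < -M_PI) d += 2.0 * M_PI;
    total += d;
    prev_arg = a;
  }
  return (int)std::lround(total / M_PI);
}

}  // namespace

// Random-walk Metropolis-Hastings over the loop gains (optionally also
// alpha, beta, t0) against a normalized observed log spectrum.
//
// Likelihood: exp(-chi2 / 2) with flat priors inside [lo, hi]; proposals
// Gaussian, reflected at the bounds; spectrally unstable states (Nyquist
// winding != 0 or a quasi-singular loop denominator) carry zero
// likelihood. Stability is evaluated lazily, only for proposals that pass
// the chi-square ratio test, which is equivalent and much cheaper.
// Proposal scales adapt toward target_accept during burn-in only. Uses
// R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List mh_kernel(NumericVector freqs, NumericVector log_obs,
               NumericVector weights, NumericVector lo, NumericVector hi,
               NumericVector init, NumericVector scales0,
               double alpha0, double beta0, double gamma_e, double t00,
               bool fit_rates, int n_iter, int burn_in, int thin,
               bool adapt, double target_accept,
               double stab_f_max = 150.0, int stab_n = 3000) {
  const int nf = freqs.size();
  const int np = init.size();
  std::vector<double> th(init.begin(), init.end());
  std::vector<double> scales(scales0.begin(), scales0.end());
  std::vector<double> power(nf), fvec(freqs.begin(), freqs.end());
  std::vector<double> dfreq(nf - 1);
  for (int j = 0; j + 1 < nf; ++j) dfreq[j] = freqs[j + 1] - freqs[j];
  const bool use_w = weights.size() == nf;

  std::vector<double> svec(stab_n);
  for (int j = 0; j < stab_n; ++j) svec[j] = stab_f_max * (j + 1) / stab_n;

  Grid pgrid, sgrid;
  pgrid.build(fvec, alpha0, beta0, gamma_e, t00);
  sgrid.build(svec, alpha0, beta0, gamma_e, t00);

  auto rebuild = [&](const std::vector<double>& t) {
    if (fit_rates) {
      pgrid.build(fvec, t[5], t[6], gamma_e, t[7]);
      sgrid.build(svec, t[5], t[6], gamma_e, t[7]);
    }
  };

  auto chi2_of = [&](const std::vector<double>& t) {
    if (dc_loop(t.data()) <= 1e-6) return R_PosInf;
    double den_min = R_PosInf;
    for (int j = 0; j < nf; ++j) {
      double dm;
      power[j] = pgrid.power(j, t.data(), &dm);
      if (dm < den_min) den_min = dm;
      if (!std::isfinite(power[j]) || power[j] <= 0.0) return R_PosInf;
    }
    if (den_min <= 1e-4) return R_PosInf;
    double tot = 0.0;
    for (int j = 0; j + 1 < nf; ++j) {
      tot += 0.5 * (power[j] + power[j + 1]) * dfreq[j];
    }
    if (!std::isfinite(tot) || tot <= 0.0) return R_PosInf;
    const double ltot = std::log(tot);
    double s = 0.0;
    for (int j = 0; j < nf; ++j) {
      const double d = log_obs[j] - (std::log(power[j]) - ltot);
      s += use_w ? d * d / weights[j] : d * d;
    }
    return s;
  };

  rebuild(th);
  double chi2_cur = chi2_of(th);
  if (!std::isfinite(chi2_cur) || winding_pre(sgrid, th.data()) != 0) {
    stop("initial state has an unstable model spectrum");
  }
  std::vector<double> map(th);
  double chi2_map = chi2_cur;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, np);
  int kept = 0, acc_post = 0, n_post = 0, acc_win = 0, win = 0;
  std::vector<double> prop(np);

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < np; ++j) {
      double x = th[j] + norm_rand() * scales[j];
      const double span = hi[j] - lo[j];
      const double z = (x - lo[j]) / (2.0 * span);
      double y = (z - std::floor(z)) * 2.0 * span;   // wrap into [0, 2 span)
      prop[j] = lo[j] + ((y <= span) ? y : 2.0 * span - y);
    }
    rebuild(prop);
    const double chi2_prop = chi2_of(prop);
    bool accept = false;
    if (std::isfinite(chi2_prop)) {
      accept = (chi2_prop <= chi2_cur) ||
        (unif_rand() < std::exp((chi2_cur - chi2_prop) / 2.0));
      if (accept) accept = winding_pre(sgrid, prop.data()) == 0;
    }
    if (accept) {
      th = prop;
      chi2_cur = chi2_prop;
      if (chi2_cur < chi2_map) { map = th; chi2_map = chi2_cur; }
    }
    if (it <= burn_in) {
      if (adapt) {
        acc_win += accept; ++win;
        if (win == 100) {
          const double rate = (double)acc_win / win;
          for (int j = 0; j < np; ++j) {
            scales[j] *= std::exp(0.5 * (rate - target_accept));
          }
          acc_win = 0; win = 0;
        }
      }
    } else {
      acc_post += accept; ++n_post;
      if ((it - burn_in) % thin == 0 && kept < n_keep) {
        for (int j = 0; j < np; ++j) samples(kept, j) = th[j];
        ++kept;
      }
    }
  }
  if (fit_rates) rebuild(th);  // leave grids consistent (not reused)

  return List::create(_["map"] = NumericVector(map.begin(), map.end()),
                      _["chi2_map"] = chi2_map,
                      _["samples"] = samples,
                      _["kept"] = kept,
                      _["accept_rate"] =
                        n_post > 0 ? (double)acc_post / n_post : NA_REAL);
}

// chi-square (with cheap denominator guards, no Nyquist gate) for a gain
// vector against a normalized observed log spectrum; used by the coarse
// initialization search.
// [[Rcpp::export]]
double chi2_gain_kernel(NumericVector freqs, NumericVector log_obs,
                        NumericVector weights, NumericVector th,
                        double alpha0, double beta0, double gamma_e,
                        double t00, bool fit_rates) {
  ctmodel::LoopParams p;
  p.G_ee = th[0]; p.G_ei = th[1]; p.G_ese = th[2]; p.G_esre = th[3];
  p.G_srs = th[4];
  p.alpha = fit_rates ? th[5] : alpha0;
  p.beta = fit_rates ? th[6] : beta0;
  p.t0 = fit_rates ? th[7] : t00;
  p.gamma_e = gamma_e;
  if (ctmodel::dc_loop_value(p) <= 1e-6) return R_PosInf;
  const int nf = freqs.size();
  std::vector<double> power(nf);
  double den_min = R_PosInf;
  for (int j = 0; j < nf; ++j) {
    double dm;
    power[j] = ctmodel::loop_power(p, freqs[j], &dm);
    if (dm < den_min) den_min = dm;
    if (!std::isfinite(power[j]) || power[j] <= 0.0) return R_PosInf;
  }
  if (den_min <= 1e-4) return R_PosInf;
  double tot = 0.0;
  for (int j = 0; j + 1 < nf; ++j) {
    tot += 0.5 * (power[j] + power[j + 1]) * (freqs[j + 1] - freqs[j]);
  }
  const double ltot = std::log(tot);
  const bool use_w = weights.size() == nf;
  double s = 0.0;
  for (int j = 0; j < nf; ++j) {
    const double d = log_obs[j] - (std::log(power[j]) - ltot);
    s += use_w ? d * d / weights[j] : d * d;
  }
  return s;
}
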