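#ifndef CTGAIN_CT_MODEL_H
#define CTGAIN_CT_MODEL_H

#include <complex>
#include <vector>
#include <cmath>

namespace ctmodel {

typedef std::complex<double> cplx;

struct LoopParams {
  double G_ee, G_ei, G_ese, G_esre, G_srs;
  double alpha, beta, gamma_e, t0;
};

// squared-magnitude transfer of the k = 0 linearized loop at frequency f
// (Hz); also reports the modulus of the smallest loop denominator
inline double loop_power(const LoopParams& p, double f, double* den_mod) {
  const cplx I(0.0, 1.0);
  const double w = 2.0 * M_PI * f;
  const cplx L = 1.0 / ((1.0 - I * w / p.alpha) * (1.0 - I * w / p.beta));
  const cplx L2 = L * L;
  const cplx E2 = std::exp(I * w * p.t0);
  const cplx den_srs = 1.0 - L2 * p.G_srs;
  const cplx den_ei = 1.0 - L * p.G_ei;
  const cplx wave = (1.0 - I * w / p.gamma_e) * (1.0 - I * w / p.gamma_e);
  const cplx q2re2 = wave -
    (L * p.G_ee + (L2 * p.G_ese + L2 * L * p.G_esre) * E2 / den_srs) / den_ei;
  double m = std::abs(q2re2);
  if (std::abs(den_srs) < m) m = std::abs(den_srs);
  if (std::abs(den_ei) < m) m = std::abs(den_ei);
  *den_mod = m;
  return std::norm(L2) / (std::norm(den_srs) * std::norm(den_ei) *
                          std::norm(q2re2));
}

inline double dc_loop_value(const LoopParams& p) {
  const double X0 = p.G_ee / (1.0 - p.G_ei);
  const double Y0 = (p.G_ese + p.G_esre) /
    ((1.0 - p.G_srs) * (1.0 - p.G_ei));
  return 1.0 - X0 - Y0;
}

// Nyquist winding number of the dispersion function along the real axis
// (0 = no growing modes); see stability_kernel for the derivation.
inline int nyquist_winding(const LoopParams& p, double f_max = 150.0,
                           int n_grid = 3000) {
  const cplx I(0.0, 1.0);
  const double dc = dc_loop_value(p);
  double total = 0.0;
  double prev_arg = (dc >= 0.0) ? 0.0 : M_PI;
  for (int j = 1; j <= n_grid; ++j) {
    const double w = 2.0 * M_PI * f_max * j / n_grid;
    const cplx L = 1.0 / ((1.0 - I * w / p.alpha) * (1.0 - I * w / p.beta));
    const cplx L2 = L * L;
    const cplx E2 = std::exp(I * w * p.t0);
    const cplx den_srs = 1.0 - L2 * p.G_srs;
    const cplx den_ei = 1.0 - L * p.G_ei;
    const cplx wave = (1.0 - I * w / p.gamma_e) * (1.0 - I * w / p.gamma_e);
    const cplx f = 1.0 -
      ((L * p.G_ee + (L2 * p.G_ese + L2 * L * p.G_esre) * E2 / den_srs) /
       den_ei) / wave;
    const double a = std::arg(f);
    double d = a - prev_arg;
    while (d > M_PI) d -= 2.0 * M_PI;
    while (d < -M_PI) d += 2.0 * M_PI;
    total += d;
    prev_arg = a;
  }
  return (int)std::lround(total / M_PI);  // doubled half-line phase / 2 pi
}

}  // namespace ctmodel

#endif
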