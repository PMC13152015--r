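#include <Rcpp.h>
#include "ct_model.h"
using namespace Rcpp;

typedef std::complex<double> cplx;

// Closed-form EEG power spectrum of the linearized corticothalamic loop.
//
// Populations: e (cortical excitatory), i (cortical inhibitory),
// r (reticular), s (relay). White-noise drive enters at the relay nucleus.
// L(w) is the dendritic (synaptodendritic) low-pass filter, the cortical
// wave operator contributes (1 - iw/gamma_e)^2, and thalamus<->cortex
// propagation carries a one-way delay t0/2 so loop terms pick up exp(i w t0).
//
// Returns the un-normalized power on the grid plus the minimum modulus of
// the loop denominators over the band and the zero-frequency loop value
// 1 - X - Y.
// [[Rcpp::export]]
List psd_kernel(NumericVector freq,
                double G_ee, double G_ei, double G_ese, double G_esre,
                double G_srs,
                double alpha, double beta, double gamma_e, double t0,
                int n_modes = 0, double r_e = 0.086, double L_x = 0.5) {
  const int n = freq.size();
  NumericVector power(n);
  ctmodel::LoopParams p;
  p.G_ee = G_ee; p.G_ei = G_ei; p.G_ese = G_ese; p.G_esre = G_esre;
  p.G_srs = G_srs; p.alpha = alpha; p.beta = beta; p.gamma_e = gamma_e;
  p.t0 = t0;
  double den_min = R_PosInf;

  if (n_modes <= 0) {
    for (int j = 0; j < n; ++j) {
      double dm;
      power[j] = ctmodel::loop_power(p, freq[j], &dm);
      if (dm < den_min) den_min = dm;
    }
  } else {
    // sum over spatial modes of a square cortex of side L_x
    const cplx I(0.0, 1.0);
    const double dk = 2.0 * M_PI / L_x;
    for (int j = 0; j < n; ++j) {
      const double w = 2.0 * M_PI * freq[j];
      const cplx L = 1.0 / ((1.0 - I * w / alpha) * (1.0 - I * w / beta));
      const cplx L2 = L * L;
      const cplx E2 = std::exp(I * w * t0);
      const cplx den_srs = 1.0 - L2 * G_srs;
      const cplx den_ei = 1.0 - L * G_ei;
      const cplx wave = (1.0 - I * w / gamma_e) * (1.0 - I * w / gamma_e);
      const cplx q2re2 = wave -
        (L * G_ee + (L2 * G_ese + L2 * L * G_esre) * E2 / den_srs) / den_ei;
      double m = std::abs(q2re2);
      if (std::abs(den_srs) < m) m = std::abs(den_srs);
      if (std::abs(den_ei) < m) m = std::abs(den_ei);
      if (m < den_min) den_min = m;
      double transfer2 = 0.0;
      for (int mx = -n_modes; mx <= n_modes; ++mx) {
        for (int my = -n_modes; my <= n_modes; ++my) {
          const double k2re2 = dk * dk * (mx * mx + my * my) * r_e * r_e;
          transfer2 += 1.0 / std::norm(k2re2 + q2re2);
        }
      }
      power[j] = std::norm(L2) /
        (std::norm(den_srs) * std::norm(den_ei)) * transfer2;
    }
  }

  return List::create(_["power"] = power,
                      _["den_min"] = den_min,
                      _["dc_loop"] = ctmodel::dc_loop_value(p));
}

// Nyquist stability test of the linearized loop: counts zeros of the
// dispersion function in the upper half plane (growing modes, e^{-i w t}
// convention) as the winding number of
// f(w) = q^2 r_e^2 / (1 - i w / gamma_e)^2 along the real axis. All
// component filters are damped (poles in the lower half plane) and f -> 1
// at large |w| in the upper half plane, so the argument principle applies;
// f(-w) = conj(f(w)) lets us walk 0..w_max and double the phase.
// winding == 0 means no growing modes.
// [[Rcpp::export]]
List stability_kernel(double G_ee, double G_ei, double G_ese, double G_esre,
                      double G_srs, double alpha, double beta,
                      double gamma_e, double t0,
                      double f_max = 150.0, int n_grid = 3000) {
  ctmodel::LoopParams p;
  p.G_ee = G_ee; p.G_ei = G_ei; p.G_ese = G_ese; p.G_esre = G_esre;
  p.G_srs = G_srs; p.alpha = alpha; p.beta = beta; p.gamma_e = gamma_e;
  p.t0 = t0;
  return List::create(
    _["winding"] = ctmodel::nyquist_winding(p, f_max, n_grid),
    _["dc_loop"] = ctmodel::dc_loop_value(p));
}
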