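#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic Heun integration of the four-population corticothalamic
// delay-differential system.
//
// State per population a in {e,i,r,s}: membrane potential V_a and its
// velocity W_a, driven through the second-order synaptodendritic operator
//   (1/(alpha beta)) V'' + (1/alpha + 1/beta) V' + V = sum_b nu_ab phi_b.
// The cortical excitatory field phi_e obeys the critically damped wave
// equation phi'' = gamma^2 (Q_e - phi) - 2 gamma phi'; the other
// populations follow the local approximation phi_a = Q_a.
// Thalamus<->cortex propagation is delayed by t0/2 with a linearly
// interpolated ring buffer. White noise (pre-scaled per step, sd/sqrt(dt))
// enters the relay population through nu_sn.
//
// nu is a 4x5 matrix, rows e,i,r,s; columns e,i,r,s,n (mV s).
// Returns phi_e sampled every keep_every steps.
// [[Rcpp::export]]
NumericVector simulate_ct_kernel(double Q_max, double theta, double sigma_prime,
                                 double alpha, double beta, double gamma_e,
                                 double t0, NumericMatrix nu, double phi_n,
                                 NumericVector noise, double dt,
                                 int keep_every, NumericVector V0,
                                 NumericVector phi0) {
  const int n_steps = noise.size();
  const int n_keep = n_steps / keep_every;
  NumericVector out(n_keep);

  auto sig = [&](double V) {
    return Q_max / (1.0 + std::exp(-(V - theta) / sigma_prime));
  };

  // delay ring buffers for phi_e and phi_s
  const double dlag = (t0 / 2.0) / dt;  // fractional steps of one-way delay
  const int R = (int)std::ceil(dlag) + 3;
  std::vector<double> ring_e(R), ring_s(R);

  // state: Ve We Vi Wi Vr Wr Vs Ws phie chie
  double y[10], yp[10], k1[10], k2[10];
  y[0] = V0[0]; y[2] = V0[1]; y[4] = V0[2]; y[6] = V0[3];
  y[1] = y[3] = y[5] = y[7] = 0.0;
  y[8] = phi0[0];  // steady phi_e (= Q_e at the fixed point)
  y[9] = 0.0;
  const double phis0 = sig(V0[3]);
  for (int j = 0; j < R; ++j) { ring_e[j] = y[8]; ring_s[j] = phis0; }

  const double ab = alpha * beta, apb = alpha + beta, g2 = gamma_e * gamma_e;

  // delayed value at step-position pos (may be negative early on)
  auto delayed = [&](const std::vector<double>& ring, double pos,
                     double fill, int n_now) {
    if (pos < 0.0) return fill;
    const int lo = (int)std::floor(pos);
    const double fr = pos - lo;
    const int i0 = lo % R, i1 = (lo + 1) % R;
    double v0 = ring[i0];
    double v1 = (lo + 1 > n_now) ? ring[i0] : ring[i1];
    return v0 + fr * (v1 - v0);
  };

  auto drift = [&](const double* s, double phis_d, double phie_d,
                   double xi, double* d) {
    const double Qe = s[8];                 // phi_e (field, not sigmoid)
    const double phii = sig(s[2]);
    const double phir = sig(s[4]);
    const double phis = sig(s[6]);
    const double Ie = nu(0,0)*Qe + nu(0,1)*phii + nu(0,3)*phis_d + nu(0,4)*phi_n;
    const double Ii = nu(1,0)*Qe + nu(1,1)*phii + nu(1,3)*phis_d + nu(1,4)*phi_n;
    const double Ir = nu(2,0)*phie_d + nu(2,3)*phis + nu(2,4)*phi_n;
    const double Is = nu(3,0)*phie_d + nu(3,2)*phir + nu(3,4)*(phi_n + xi);
    d[0] = s[1]; d[1] = ab * (Ie - s[0]) - apb * s[1];
    d[2] = s[3]; d[3] = ab * (Ii - s[2]) - apb * s[3];
    d[4] = s[5]; d[5] = ab * (Ir - s[4]) - apb * s[5];
    d[6] = s[7]; d[7] = ab * (Is - s[6]) - apb * s[7];
    d[8] = s[9]; d[9] = g2 * (sig(s[0]) - s[8]) - 2.0 * gamma_e * s[9];
  };

  int kout = 0;
  for (int nstep = 0; nstep < n_steps; ++nstep) {
    // record current fields into the rings
    ring_e[nstep % R] = y[8];
    ring_s[nstep % R] = sig(y[6]);

    const double xi = noise[nstep];
    const double phis_d0 = delayed(ring_s, nstep - dlag, phis0, nstep);
    const double phie_d0 = delayed(ring_e, nstep - dlag, phi0[0], nstep);
    drift(y, phis_d0, phie_d0, xi, k1);
    for (int j = 0; j < 10; ++j) yp[j] = y[j] + dt * k1[j];
    const double phis_d1 = delayed(ring_s, nstep + 1 - dlag, phis0, nstep);
    const double phie_d1 = delayed(ring_e, nstep + 1 - dlag, phi0[0], nstep);
    drift(yp, phis_d1, phie_d1, xi, k2);
    for (int j = 0; j < 10; ++j) y[j] += 0.5 * dt * (k1[j] + k2[j]);

    if (!std::isfinite(y[8]) || !std::isfinite(y[0])) {
      stop("time-domain integration diverged at t = %.3f s (step %d)",
           (nstep + 1) * dt, nstep + 1);
    }
    if ((nstep + 1) % keep_every == 0 && kout < n_keep) {
      out[kout++] = y[8];
    }
  }
  return out;
}
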