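// Single-compartment spiking-membrane integrator.
//
// State: V (mV), Kv7 gate a, delayed-rectifier gate n, Na inactivation h.
// The spike current uses an instantaneous Boltzmann activation whose
// low-voltage tail is exponential in V (exponential-onset dynamics with
// slope delta_t), saturating at high V so the action potential has a finite
// upstroke, a peak and a repolarizing downstroke.
//
// Units: mV, ms, pA, pF, nS (nS * mV = pA).

#include <Rcpp.h>
using namespace Rcpp;

struct Params {
  double C, gL, EL;
  double gNa, ENa, vm_half, delta_t;
  double gKd, EK, vn_half, kn, tau_n;
  double vh_half, kh, tau_h_rest, tau_h_spike;
  double gkv7, va_half, ka, tau_a;
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double dvdt(const Params& p, double V, double a, double n,
                          double h, double I) {
  double m = sigmoid((V - p.vm_half) / p.delta_t);
  double I_ion = -p.gL * (V - p.EL)
                 - p.gkv7 * a * (V - p.EK)
                 - p.gNa * m * h * (V - p.ENa)
                 - p.gKd * n * (V - p.EK);
  return (I_ion + I) / p.C;
}

static inline double tau_h_of(const Params& p, double V) {
  // fast inactivation at spike voltages, slow recovery near rest
  return p.tau_h_spike +
         (p.tau_h_rest - p.tau_h_spike) * sigmoid(-(V + 40.0) / 5.0);
}

// [[Rcpp::export]]
List simulate_membrane_cpp(NumericVector I_inj, double dt,
                           List par, double v0, double a0, double n0,
                           double h0, double noise_sigma, double tau_ou,
                           double spike_cross = 0.0) {
  Params p;
  p.C = par["C"]; p.gL = par["g_leak"]; p.EL = par["E_leak"];
  p.gNa = par["g_na"]; p.ENa = par["E_na"];
  p.vm_half = par["vm_half"]; p.delta_t = par["delta_t"];
  p.gKd = par["g_kd"]; p.EK = par["E_K"];
  p.vn_half = par["vn_half"]; p.kn = par["kn"]; p.tau_n = par["tau_n"];
  p.vh_half = par["vh_half"]; p.kh = par["kh"];
  p.tau_h_rest = par["tau_h_rest"]; p.tau_h_spike = par["tau_h_spike"];
  p.gkv7 = par["g_kv7_max"]; p.va_half = par["kv7_vhalf"];
  p.ka = par["kv7_k"]; p.tau_a = par["tau_kv7"];

  int nstep = I_inj.size();
  NumericVector V(nstep);
  std::vector<double> spikes;
  double v = v0, a = a0, n = n0, h = h0, iou = 0.0;
  double ou_decay = (tau_ou > 0) ? std::exp(-dt / tau_ou) : 0.0;
  double ou_sd = (noise_sigma > 0)
                     ? noise_sigma * std::sqrt(1.0 - ou_decay * ou_decay)
                     : 0.0;
  RNGScope scope;
  V[0] = v;
  for (int i = 1; i < nstep; ++i) {
    if (noise_sigma > 0) iou = ou_decay * iou + ou_sd * R::norm_rand();
    double I = I_inj[i - 1] + iou;
    // RK4 for V with gates frozen within the step
    double k1 = dvdt(p, v, a, n, h, I);
    double k2 = dvdt(p, v + 0.5 * dt * k1, a, n, h, I);
    double k3 = dvdt(p, v + 0.5 * dt * k2, a, n, h, I);
    double k4 = dvdt(p, v + dt * k3, a, n, h, I);
    double v_new = v + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    // gates: exact exponential relaxation toward their steady state at v
    double a_inf = sigmoid((v - p.va_half) / p.ka);
    double n_inf = sigmoid((v - p.vn_half) / p.kn);
    double h_inf = 1.0 - sigmoid((v - p.vh_half) / p.kh);
    if (p.tau_a > 0) a += (a_inf - a) * (1.0 - std::exp(-dt / p.tau_a));
    else a = a_inf;
    n += (n_inf - n) * (1.0 - std::exp(-dt / p.tau_n));
    double th = tau_h_of(p, v);
    h += (h_inf - h) * (1.0 - std::exp(-dt / th));
    if (!std::isfinite(v_new) || v_new > 80.0 || v_new < -150.0)
      stop("membrane integration unstable at step %d (V=%g mV)", i, v_new);
    if (v < spike_cross && v_new >= spike_cross) {
      double frac = (spike_cross - v) / (v_new - v);
      spikes.push_back((i - 1 + frac) * dt);
    }
    v = v_new;
    V[i] = v;
  }
  return List::create(_["v"] = V, _["spike_times"] = NumericVector(wrap(spikes)));
}
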