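#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classic squid-axon Hodgkin-Huxley point neuron, forward Euler.
// Units: mV, ms, uA/cm^2, mS/cm^2.  Spike times (ms) are upward crossings
// of 0 mV, linearly interpolated between steps.

static inline double am(double V) {
  double x = V + 40.0;
  return (std::fabs(x) < 1e-7) ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bm(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double ah(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double bh(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double an(double V) {
  double x = V + 55.0;
  return (std::fabs(x) < 1e-7) ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bn(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

// [[Rcpp::export]]
List simulate_hh_cpp(double I0, double pulse_t, double pulse_w,
                     double pulse_amp, double dt, double duration,
                     bool return_v) {
  const double gNa = 120.0, gK = 36.0, gL = 0.3;
  const double ENa = 50.0, EK = -77.0, EL = -54.387, Cm = 1.0;
  double V = -65.0;
  double m = am(V) / (am(V) + bm(V));
  double h = ah(V) / (ah(V) + bh(V));
  double n = an(V) / (an(V) + bn(V));

  const int n_steps = (int)std::ceil(duration / dt);
  std::vector<double> spikes;
  NumericVector Vout = return_v ? NumericVector(n_steps + 1) : NumericVector(0);
  if (return_v) Vout[0] = V;
  bool gating_ok = true;

  for (int s = 1; s <= n_steps; ++s) {
    const double t = (s - 1) * dt;  // current applied over [t, t+dt)
    double I = I0;
    if (pulse_amp != 0.0 && t >= pulse_t && t < pulse_t + pulse_w) I += pulse_amp;
    const double Vp = V;
    const double INa = gNa * m * m * m * h * (Vp - ENa);
    const double IK = gK * n * n * n * n * (Vp - EK);
    const double IL = gL * (Vp - EL);
    V += dt * (I - INa - IK - IL) / Cm;
    m += dt * (am(Vp) * (1.0 - m) - bm(Vp) * m);
    h += dt * (ah(Vp) * (1.0 - h) - bh(Vp) * h);
    n += dt * (an(Vp) * (1.0 - n) - bn(Vp) * n);
    if (m < -1e-9 || m > 1.0 + 1e-9 || h < -1e-9 || h > 1.0 + 1e-9 ||
        n < -1e-9 || n > 1.0 + 1e-9) gating_ok = false;
    if (m < 0.0) m = 0.0; if (m > 1.0) m = 1.0;
    if (h < 0.0) h = 0.0; if (h > 1.0) h = 1.0;
    if (n < 0.0) n = 0.0; if (n > 1.0) n = 1.0;
    if (Vp < 0.0 && V >= 0.0) {
      const double frac = -Vp / (V - Vp);
      spikes.push_back((s - 1) * dt + frac * dt);
    }
    if (return_v) Vout[s] = V;
  }
  List out = List::create(
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
      _["gating_ok"] = gating_ok);
  if (return_v) out["V"] = Vout;
  return out;
}
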