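#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_pi(double x) {
  // avoids fmod (versioned symbol in recent glibc)
  const double twopi = 2.0 * M_PI;
  return x - twopi * std::floor((x + M_PI) / twopi);
}

// Euler--Maruyama integration of the finite Kuramoto network with an
// optional phase-triggered pulse controller.  Coupling uses the exact
// mean-field identity (K/N) sum_j sin(theta_j - theta_i) =
// K * rho * sin(psi - theta_i); the per-oscillator phase-response function
// is fixed to Z(theta) = -sin(theta) on this fast path.
// Draws from R's RNG so results are governed by set.seed().
//
// on_start/on_end: stimulation-enabled intervals (s), sorted, non-overlapping.
// refractory_s: minimum inter-pulse time (s); rho_gate: controller is
// suppressed while rho < rho_gate (mean phase meaningless).
// [[Rcpp::export]]
List simulate_kuramoto_cpp(NumericVector theta0, NumericVector omega,
                           double K, double D, double dt, int n_steps,
                           bool stim_enabled, double I_pulse,
                           double target_phase, double refractory_s,
                           double rho_gate,
                           NumericVector on_start, NumericVector on_end,
                           bool store_theta) {
  const int N = theta0.size();
  if (omega.size() != N) stop("theta0 and omega must have equal length");
  std::vector<double> theta(theta0.begin(), theta0.end());

  NumericVector times(n_steps + 1), rho_s(n_steps + 1), psi_s(n_steps + 1);
  std::vector<double> pulses;
  NumericMatrix theta_out = store_theta ? NumericMatrix(n_steps + 1, N)
                                        : NumericMatrix(0, 0);

  const double sn = std::sqrt(2.0 * D * dt);
  const int n_ep = on_start.size();
  int ep = 0;  // pointer into epochs
  double last_pulse = -1e18;

  double S = 0.0, C = 0.0;
  for (int i = 0; i < N; ++i) { S += std::sin(theta[i]); C += std::cos(theta[i]); }
  double rho = std::sqrt(S * S + C * C) / N;
  double psi = (rho < 1e-12) ? 0.0 : std::atan2(S, C);
  times[0] = 0.0; rho_s[0] = rho; psi_s[0] = psi;
  if (store_theta) for (int i = 0; i < N; ++i) theta_out(0, i) = wrap_pi(theta[i]);

  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    const double t = s * dt;
    const double rho_p = rho, psi_p = psi;
    if (D > 0.0) {
      for (int i = 0; i < N; ++i)
        theta[i] += dt * (omega[i] + K * rho_p * std::sin(psi_p - theta[i]))
                    + sn * norm_rand();
    } else {
      for (int i = 0; i < N; ++i)
        theta[i] += dt * (omega[i] + K * rho_p * std::sin(psi_p - theta[i]));
    }
    S = 0.0; C = 0.0;
    for (int i = 0; i < N; ++i) { S += std::sin(theta[i]); C += std::cos(theta[i]); }
    rho = std::sqrt(S * S + C * C) / N;
    psi = (rho < 1e-12) ? 0.0 : std::atan2(S, C);

    if (stim_enabled && rho > rho_gate && rho_p > rho_gate) {
      while (ep < n_ep && t > on_end[ep]) ++ep;
      if (ep < n_ep && t >= on_start[ep] && t <= on_end[ep]) {
        const double d_prev = wrap_pi(psi_p - target_phase);
        const double d_cur = wrap_pi(psi - target_phase);
        // upward crossing through the target (not the +/- pi wrap point)
        if (d_prev < 0.0 && d_cur >= 0.0 && (d_cur - d_prev) < M_PI &&
            (t - last_pulse) > refractory_s) {
          for (int i = 0; i < N; ++i)
            theta[i] += I_pulse * (-std::sin(theta[i]));
          S = 0.0; C = 0.0;
          for (int i = 0; i < N; ++i) { S += std::sin(theta[i]); C += std::cos(theta[i]); }
          rho = std::sqrt(S * S + C * C) / N;
          psi = (rho < 1e-12) ? 0.0 : std::atan2(S, C);
          pulses.push_back(t);
          last_pulse = t;
        }
      }
    }

    times[s] = t; rho_s[s] = rho; psi_s[s] = psi;
    if (store_theta) for (int i = 0; i < N; ++i) theta_out(s, i) = wrap_pi(theta[i]);
  }

  List out = List::create(_["times"] = times, _["rho"] = rho_s, _["psi"] = psi_s,
                          _["pulse_times"] = NumericVector(pulses.begin(), pulses.end()));
  if (store_theta) out["theta"] = theta_out;
  return out;
}

// Direct-form-II-transposed IIR filter; a[0] must be 1 (normalized upstream).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int k = 0; k < n; ++k) {
    const double xk = x[k];
    const double yk = bb[0] * xk + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xk + z[i + 1] - aa[i + 1] * yk;
    if (nz > 0) z[nz - 1] = bb[nz] * xk - aa[nz] * yk;
    y[k] = yk;
  }
  return y;
}
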