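#include <Rcpp.h>
using namespace Rcpp;

// Coupled tri-compartment state, fixed order:
//   0 r, 1 e, 2 V_N, 3 n, 4 m, 5 h, 6 V_A,
//   7 K_o, 8 K_n, 9 K_a, 10 Na_o, 11 Na_n, 12 Na_a
#define NSTATE 13

struct ModelP {
  double tau_rec, tau_inac, A_se, U_se, syn_scale;
  double g_Na, g_K, g_lN, V_lN, V_rest, C_N;
  double G_kir, V_A1, V_A2, V_A3, C_A, g_lA, V_lA;
  double gamma_N, gamma_A, i_maxN, i_maxA, vr_N, vr_A;
  double i_NalN, i_NalA, comp_flux;
  double RTF;
  int kir_on;
};

// x / (exp(x/10) - 1), with the removable singularity at x = 0
static inline double hh_ratio(double x) {
  if (std::fabs(x) < 1e-7) return 10.0;
  return x / expm1(0.1 * x);
}

static inline double pump_factor(double K_o, double Na_in) {
  double a = 1.0 + 7.3 / K_o, b = 1.0 + 10.0 / Na_in;
  return 1.0 / (a * a * b * b * b);
}

static void derivs(const double* y, double I_app, const ModelP& p, double* dy,
                   double* I_Kir_out, double* uptake_out) {
  const double r = y[0], e = y[1], V_N = y[2], n = y[3], m = y[4], h = y[5];
  const double V_A = y[6], K_o = y[7], K_n = y[8], K_a = y[9];
  const double Na_o = y[10], Na_n = y[11], Na_a = y[12];

  // three-state synaptic resources (continuous part; impulses jump outside)
  dy[0] = (1.0 - r - e) / p.tau_rec;
  dy[1] = -e / p.tau_inac;

  // HH gating on the displacement u = V_rest - V_N (original convention)
  const double u = p.V_rest - V_N;
  const double a_n = 0.01 * hh_ratio(u + 10.0);
  const double b_n = 0.125 * exp(u / 80.0);
  const double a_m = 0.1 * hh_ratio(u + 25.0);
  const double b_m = 4.0 * exp(u / 18.0);
  const double a_h = 0.07 * exp(u / 20.0);
  const double b_h = 1.0 / (exp(0.1 * (u + 30.0)) + 1.0);
  dy[3] = a_n * (1.0 - n) - b_n * n;
  dy[4] = a_m * (1.0 - m) - b_m * m;
  dy[5] = a_h * (1.0 - h) - b_h * h;

  // membrane currents (outward positive), dynamic Nernst potentials
  const double E_Na = p.RTF * log(Na_o / Na_n);
  const double E_K  = p.RTF * log(K_o / K_n);
  const double I_Na = p.g_Na * m * m * m * h * (V_N - E_Na);
  const double I_K  = p.g_K * n * n * n * n * (V_N - E_K);
  const double I_lN = p.g_lN * (V_N - p.V_lN);
  dy[2] = (-(I_Na + I_K + I_lN) + I_app) / p.C_N;

  // astrocyte: Kir4.1 (sqrt([K+]o) x Boltzmann gating) + leak
  const double V_KA = p.RTF * log(K_o / K_a);
  double I_Kir = 0.0;
  if (p.kir_on) {
    I_Kir = p.G_kir * (V_A - V_KA - p.V_A1) * sqrt(K_o) /
            (1.0 + exp((V_A - V_KA - p.V_A2) / p.V_A3));
    dy[6] = -(I_Kir + p.g_lA * (V_A - p.V_lA)) / p.C_A;
  } else {
    dy[6] = 0.0;  // Kir blocked: current and leak clamped off, V_A frozen
  }

  // Na/K pumps (2 K+ in : 3 Na+ out) and current-to-flux conversions
  const double ip_N = p.i_maxN * pump_factor(K_o, Na_n);
  const double ip_A = p.i_maxA * pump_factor(K_o, Na_a);
  const double i_K = p.gamma_N * I_K;
  const double i_Na = p.gamma_N * I_Na;
  const double i_Kir = p.kir_on ? p.gamma_A * I_Kir : p.comp_flux;

  dy[7]  = i_K - 2.0 * ip_N - 2.0 * ip_A + i_Kir;
  dy[8]  = (-i_K + 2.0 * ip_N) * p.vr_N;
  dy[9]  = (-i_Kir + 2.0 * ip_A) * p.vr_A;
  dy[10] = i_Na + p.i_NalN + 3.0 * ip_N + 3.0 * ip_A + p.i_NalA;
  dy[11] = (-i_Na - 3.0 * ip_N - p.i_NalN) * p.vr_N;
  dy[12] = (-p.i_NalA - 3.0 * ip_A) * p.vr_A;

  if (I_Kir_out) *I_Kir_out = I_Kir;
  if (uptake_out) *uptake_out = 2.0 * ip_A - i_Kir;
}

static ModelP unpack(const NumericVector& pv) {
  ModelP p;
  p.tau_rec = pv["tau_rec"];   p.tau_inac = pv["tau_inac"];
  p.A_se = pv["A_se"];         p.U_se = pv["U_se"];
  p.syn_scale = pv["syn_scale"];
  p.g_Na = pv["g_Na"];         p.g_K = pv["g_K"];
  p.g_lN = pv["g_lN"];         p.V_lN = pv["V_lN"];
  p.V_rest = pv["V_rest"];     p.C_N = pv["C_N"];
  p.G_kir = pv["G_kir"];       p.V_A1 = pv["V_A1"];
  p.V_A2 = pv["V_A2"];         p.V_A3 = pv["V_A3"];
  p.C_A = pv["C_A"];           p.g_lA = pv["g_lA"];
  p.V_lA = pv["V_lA"];
  p.gamma_N = pv["gamma_N"];   p.gamma_A = pv["gamma_A"];
  p.i_maxN = pv["i_maxN"];     p.i_maxA = pv["i_maxA"];
  p.vr_N = pv["vr_N"];         p.vr_A = pv["vr_A"];
  p.i_NalN = pv["i_NalN"];     p.i_NalA = pv["i_NalA"];
  p.comp_flux = pv["comp_flux"];
  p.RTF = pv["RTF"];           p.kir_on = (int) pv["kir_on"];
  return p;
}

// [[Rcpp::export(name = ".sim_core")]]
NumericMatrix sim_core(NumericVector pv, NumericVector y0, double dt, int n_steps,
                       IntegerVector impulse_steps,
                       double pulse_amp, double pulse_width_ms, IntegerVector pulse_steps,
                       double noise_sigma, double noise_gain, int record_every) {
  ModelP p = unpack(pv);
  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], yt[NSTATE];
  if (y0.size() != NSTATE) stop("state vector must have %d elements", NSTATE);
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 17);

  std::vector<char> imp(n_steps + 1, 0);
  for (int k = 0; k < impulse_steps.size(); ++k) {
    int s = impulse_steps[k];
    if (s >= 0 && s <= n_steps) imp[s] = 1;
  }
  const int pw = (int) std::lround(pulse_width_ms / dt);
  std::vector<char> pul(n_steps + 1, 0);
  for (int k = 0; k < pulse_steps.size(); ++k) {
    int s = pulse_steps[k];
    for (int j = 0; j < pw; ++j)
      if (s + j >= 0 && s + j <= n_steps) pul[s + j] = 1;
  }
  const bool use_pulse = pulse_steps.size() > 0;
  const double noise_scale =
      (noise_sigma > 0) ? sqrt(noise_sigma * noise_gain * dt) / p.C_N : 0.0;
  RNGScope scope;

  int ri = 0;
  for (int s = 0; s <= n_steps; ++s) {
    if (imp[s]) {  // jump-then-flow: impulse moves U_se * r from r to e
      double jump = p.U_se * y[0];
      y[0] -= jump;
      y[1] += jump;
    }
    double I_app = use_pulse ? (pul[s] ? pulse_amp : 0.0)
                             : p.syn_scale * p.A_se * y[1];
    if (s % record_every == 0 && ri < n_rec) {
      double I_Kir, upt, dy[NSTATE];
      derivs(y, I_app, p, dy, &I_Kir, &upt);
      out(ri, 0) = s * dt;
      for (int i = 0; i < NSTATE; ++i) out(ri, i + 1) = y[i];
      out(ri, 14) = I_app;
      out(ri, 15) = I_Kir;
      out(ri, 16) = upt;
      ++ri;
    }
    if (s == n_steps) break;

    // classical RK4 for the deterministic part
    derivs(y, I_app, p, k1, nullptr, nullptr);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    double I_mid = use_pulse ? (pul[s] ? pulse_amp : 0.0)
                             : p.syn_scale * p.A_se * yt[1];
    derivs(yt, I_mid, p, k2, nullptr, nullptr);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    I_mid = use_pulse ? (pul[s] ? pulse_amp : 0.0) : p.syn_scale * p.A_se * yt[1];
    derivs(yt, I_mid, p, k3, nullptr, nullptr);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + dt * k3[i];
    double I_end = use_pulse ? (pul[s] ? pulse_amp : 0.0)
                             : p.syn_scale * p.A_se * yt[1];
    derivs(yt, I_end, p, k4, nullptr, nullptr);
    for (int i = 0; i < NSTATE; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // Euler-Maruyama white-noise current, split after the RK4 update
    if (noise_scale > 0) y[2] += noise_scale * norm_rand();

    for (int i = 0; i < NSTATE; ++i) {
      if (!std::isfinite(y[i])) {
        stop("integration diverged at t = %.1f ms (state %d)", (s + 1) * dt, i + 1);
      }
    }
  }
  return out;
}
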