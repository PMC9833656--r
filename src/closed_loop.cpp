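// Closed-loop digital-twin core: electromagnet + Kelvin-Voigt sample +
// linear-CCD shadow sensor + adaptive pole-placement PID, integrated with
// fixed-substep RK4 between 200 Hz control ticks. Mirrors the R-level
// module functions exactly (they are the documented contracts); kept in
// C++ so long protocols run in milliseconds.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Plant {
  double F0, x0, d3;          // magnet
  double l0, A, k, c;         // sample
  bool nonlinear; double E0, B;
  double m, c_d;              // moving body
  double x_start;
  double spring(double q) const {
    if (q < 0) return 0.0;
    if (!nonlinear) return k * q;
    double eps = q / l0;
    double sigma = (B == 0.0) ? E0 * eps : (E0 / B) * (std::exp(B * eps) - 1.0);
    return A * sigma;
  }
  double coil(double x, double I) const {
    return F0 * I * I * d3 * std::exp(-x / x0);
  }
  // dq/dt = v ; dv/dt = (F_E - spring - (c + c_d) v) / m
  void deriv(double q, double v, double I, double& dq, double& dv) const {
    double x = x_start - q;
    if (x < 0) x = 0;
    double F = coil(x, I) - spring(q) - (c + c_d) * v;
    dq = v;
    dv = F / m;
  }
};

struct Sensor {
  int n_pixels, adc_bits, delay_frames;
  double pitch, magnification, noise_sd, bright, dark;
  double s0;                  // object-plane position imaged at sensor center
  double bead_d;
  double adc_max() const { return std::pow(2.0, adc_bits) - 1.0; }

  double quantize(double v) const {
    double lo = 0.0, hi = adc_max();
    double r = ::Rf_fround(v, 0);           // match R's round()
    return std::min(hi, std::max(lo, r));
  }
  // Render one pixel (1-based index) given shadow edges [a, b] in px units.
  double pixel(int i, double a, double b, bool noisy) const {
    double frac = std::min(static_cast<double>(i), b) -
                  std::max(static_cast<double>(i) - 1.0, a);
    frac = std::max(0.0, std::min(1.0, frac));
    double v = bright - frac * (bright - dark);
    if (noisy && noise_sd > 0) v += noise_sd * ::norm_rand();
    return quantize(v);
  }
  // Occluded fraction inferred from a rendered ADU value.
  double occ(double v) const {
    double f = (bright - v) / (bright - dark);
    return std::max(0.0, std::min(1.0, f));
  }
  // Render the edge neighborhoods of the shadow of a bead centered at
  // object-plane position s and localize it. Pixels far from the edges sit
  // exactly on a plateau (noise there cannot cross the mid-threshold at the
  // default contrast-to-noise ratio), so only +/-16 px windows around each
  // edge are rendered with noise. Returns the estimated center in
  // object-plane meters; ok=false on an off-sensor shadow.
  double locate(double s, bool& ok) {
    double a = magnification * (s - bead_d / 2.0) / pitch;
    double b = magnification * (s + bead_d / 2.0) / pitch;
    if (a < 2.0 || b > n_pixels - 2.0) { ok = false; return NA_REAL; }
    double thr = (bright + dark) / 2.0;
    const int W = 16;
    int la = std::max(1, static_cast<int>(std::floor(a)) - W + 1);
    int ra = std::min(n_pixels, static_cast<int>(std::floor(a)) + W);
    int lb = std::max(1, static_cast<int>(std::floor(b)) - W + 1);
    int rb = std::min(n_pixels, static_cast<int>(std::floor(b)) + W);
    std::vector<double> wa(ra - la + 1), wb(rb - lb + 1);
    for (int i = la; i <= ra; ++i) wa[i - la] = pixel(i, a, b, true);
    for (int i = lb; i <= rb; ++i) wb[i - lb] = pixel(i, a, b, true);
    int k1 = -1, k2 = -1;
    for (int i = la; i <= ra; ++i)
      if (wa[i - la] < thr) { k1 = i; break; }
    for (int i = rb; i >= lb; --i)
      if (wb[i - lb] < thr) { k2 = i; break; }
    if (k1 < 0 || k2 < 0 || k2 <= k1) { ok = false; return NA_REAL; }
    double v_k1 = wa[k1 - la];
    double v_k1m = (k1 - 1 >= la) ? wa[k1 - 1 - la] : bright;
    double v_k2 = wb[k2 - lb];
    double v_k2p = (k2 + 1 <= rb) ? wb[k2 + 1 - lb] : bright;
    double a_px = k1 - occ(v_k1) - occ(v_k1m);
    double b_px = (k2 - 1) + occ(v_k2) + occ(v_k2p);
    ok = true;
    return (a_px + b_px) / 2.0 * pitch / magnification;
  }
};

struct Gains { double Kp, Ki, Kd; bool bootstrap; };

struct Controller {
  double a2, a1, a0;          // desired monic coefficients
  double Ki_max, I_max, I_clamp;
  double bKp, bKi, bKd;       // bootstrap gains
  double k_hat_max, q_min, c_hat;
  double I_op_min, deriv_tau, k_hat_tau;
  double dt;

  double raw_k_hat(double F_bar, double q_meas) const {
    if (q_meas < q_min) return 0.0;
    return std::min(std::max(F_bar / q_meas, 0.0), k_hat_max);
  }
  Gains update(double x_meas, double I_prev, double q_meas, double k_hat,
               const Plant& p) const {
    Gains g;
    double I_lin = std::max(I_prev, I_op_min);
    if (I_lin <= 0) { g = {bKp, bKi, bKd, true}; return g; }
    double F_bar = p.coil(x_meas, std::min(I_lin, I_max));
    double KI = 2.0 * F_bar / I_lin;
    if (KI <= 0) { g = {bKp, bKi, bKd, true}; return g; }
    double k_eff = k_hat - F_bar / p.x0;
    double c_t = c_hat + p.c_d;
    g.Kd = (p.m * a2 - c_t) / KI;
    g.Kp = (p.m * a1 - k_eff) / KI;
    g.Ki = std::min(p.m * a0 / KI, Ki_max);
    g.bootstrap = false;
    return g;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_closed_loop_core")]]
List run_closed_loop_core(NumericVector q_ref, List plant_cfg,
                          List sensor_cfg, List ctrl_cfg,
                          double I_init, int n_sub) {
  Plant p;
  p.F0 = plant_cfg["F0"]; p.x0 = plant_cfg["x0"];
  double d = plant_cfg["d"]; p.d3 = d * d * d;
  p.l0 = plant_cfg["l0"]; p.A = plant_cfg["A"];
  p.k = plant_cfg["k"]; p.c = plant_cfg["c"];
  p.nonlinear = plant_cfg["nonlinear"];
  p.E0 = plant_cfg["E0"]; p.B = plant_cfg["B"];
  p.m = plant_cfg["m"]; p.c_d = plant_cfg["c_d"];
  p.x_start = plant_cfg["x_start"];

  Sensor s;
  s.n_pixels = sensor_cfg["n_pixels"]; s.pitch = sensor_cfg["pitch"];
  s.adc_bits = sensor_cfg["adc_bits"];
  s.magnification = sensor_cfg["magnification"];
  s.noise_sd = sensor_cfg["noise_sd"];
  s.delay_frames = sensor_cfg["delay_frames"];
  s.bright = sensor_cfg["bright_level"]; s.dark = sensor_cfg["dark_level"];
  s.s0 = sensor_cfg["s0"]; s.bead_d = d;

  Controller ctl;
  ctl.a2 = ctrl_cfg["a2"]; ctl.a1 = ctrl_cfg["a1"]; ctl.a0 = ctrl_cfg["a0"];
  ctl.Ki_max = ctrl_cfg["Ki_max"]; ctl.I_max = ctrl_cfg["I_max"];
  ctl.I_clamp = ctrl_cfg["I_clamp"];
  ctl.bKp = ctrl_cfg["bKp"]; ctl.bKi = ctrl_cfg["bKi"];
  ctl.bKd = ctrl_cfg["bKd"];
  ctl.k_hat_max = ctrl_cfg["k_hat_max"]; ctl.q_min = ctrl_cfg["q_min"];
  ctl.c_hat = ctrl_cfg["c_hat"]; ctl.dt = ctrl_cfg["dt"];
  ctl.I_op_min = ctrl_cfg["I_op_min"]; ctl.deriv_tau = ctrl_cfg["deriv_tau"];
  ctl.k_hat_tau = ctrl_cfg["k_hat_tau"];

  const int N = q_ref.size();
  NumericVector t(N), q_true_v(N), q_meas_v(N), I_v(N), FE_v(N),
      Fs_v(N), Fd_v(N), Kp_v(N), Ki_v(N), Kd_v(N), khat_v(N);
  IntegerVector flags(N);

  RNGScope rng;

  // state
  double q = 0.0, v = 0.0;
  double integ = I_init, prev_meas = NA_REAL, prev_e = 0.0, deriv_f = 0.0;
  double k_hat_f = 0.0;
  const double beta = ctl.deriv_tau / (ctl.deriv_tau + ctl.dt);
  const double gamma = ctl.k_hat_tau / (ctl.k_hat_tau + ctl.dt);
  double I_prev = I_init, last_est = 0.0;
  std::vector<double> delay_buf;   // raw estimates, newest last
  int status = 0, n_done = N;

  const double dt = ctl.dt;
  const double h = dt / n_sub;

  for (int n = 0; n < N; ++n) {
    // --- sense: frame of the current true position, then delay ---
    bool ok = true;
    double est = s.locate(s.s0 + q, ok);
    bool dropped = !ok;
    if (!ok) est = last_est;
    last_est = est;
    delay_buf.push_back(est);
    int idx = static_cast<int>(delay_buf.size()) - 1 - s.delay_frames;
    if (idx < 0) idx = 0;
    double q_meas = delay_buf[idx] - s.s0;

    // --- adapt gains at the measured operating point ---
    double x_meas = p.x_start - q_meas;
    if (x_meas < 0) x_meas = 0;
    // stiffness secant is conditioned on the commanded reference (not the
    // fed-back measurement: dividing by the measurement closes a parametric
    // feedback loop, dk/dq ~ -F/q^2 times the tracking error, that
    // destabilizes stiff samples). On overshoot the measurement is the
    // larger of the two and taking it avoids inflating the estimate while
    // the reference shrinks under a still-held force.
    double I_lin = std::max(I_prev, ctl.I_op_min);
    double F_lin = (I_lin > 0)
        ? p.coil(x_meas, std::min(I_lin, ctl.I_max)) : 0.0;
    double q_den = std::max(q_ref[n], q_meas);
    k_hat_f = gamma * k_hat_f + (1.0 - gamma) * ctl.raw_k_hat(F_lin, q_den);
    Gains g = ctl.update(x_meas, I_prev, q_meas, k_hat_f, p);

    // --- PID step (derivative on measurement, conditional integration) ---
    double e = q_ref[n] - q_meas;
    double deriv_raw = ISNA(prev_meas) ? 0.0 : -(q_meas - prev_meas) / dt;
    double deriv = beta * deriv_f + (1.0 - beta) * deriv_raw;
    deriv_f = deriv;
    double integ_new = integ + g.Ki * (e + prev_e) / 2.0 * dt;
    integ_new = std::min(ctl.I_clamp, std::max(-ctl.I_clamp, integ_new));
    double u_raw = g.Kp * e + integ_new + g.Kd * deriv;
    double u = std::min(ctl.I_max, std::max(0.0, u_raw));
    bool sat = (u_raw > ctl.I_max) || (u_raw < 0.0);
    if ((u_raw > ctl.I_max && e > 0) || (u_raw < 0.0 && e < 0))
      integ_new = integ;                 // freeze while saturated
    integ = integ_new; prev_meas = q_meas; prev_e = e;
    double I_cmd = u;

    // --- record ---
    double x_true = std::max(0.0, p.x_start - q);
    t[n] = n * dt;
    q_true_v[n] = q; q_meas_v[n] = q_meas; I_v[n] = I_cmd;
    FE_v[n] = p.coil(x_true, I_cmd);
    Fs_v[n] = p.spring(q) + p.c * v;
    Fd_v[n] = -p.c_d * v;
    Kp_v[n] = g.Kp; Ki_v[n] = g.Ki; Kd_v[n] = g.Kd; khat_v[n] = k_hat_f;
    flags[n] = (sat ? 1 : 0) | (dropped ? 2 : 0) | (q < 0 ? 4 : 0);

    // --- integrate to the next tick (zero-order-hold current) ---
    for (int ss = 0; ss < n_sub; ++ss) {
      double k1q, k1v, k2q, k2v, k3q, k3v, k4q, k4v;
      p.deriv(q, v, I_cmd, k1q, k1v);
      p.deriv(q + h / 2 * k1q, v + h / 2 * k1v, I_cmd, k2q, k2v);
      p.deriv(q + h / 2 * k2q, v + h / 2 * k2v, I_cmd, k3q, k3v);
      p.deriv(q + h * k3q, v + h * k3v, I_cmd, k4q, k4v);
      q += h / 6 * (k1q + 2 * k2q + 2 * k3q + k4q);
      v += h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v);
    }
    I_prev = I_cmd;
    if (!std::isfinite(q) || std::fabs(q) > 10 * p.l0) {
      status = 1; n_done = n + 1;
      break;
    }
  }

  Range keep(0, n_done - 1);
  return List::create(
      _["t_s"] = t[keep], _["q_true_m"] = q_true_v[keep],
      _["q_meas_m"] = q_meas_v[keep], _["I_A"] = I_v[keep],
      _["F_E_N"] = FE_v[keep], _["F_spring_N"] = Fs_v[keep],
      _["F_drag_N"] = Fd_v[keep],
      _["Kp"] = Kp_v[keep], _["Ki"] = Ki_v[keep], _["Kd"] = Kd_v[keep],
      _["k_hat"] = khat_v[keep],
      _["flags"] = flags[keep], _["status"] = status);
}
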