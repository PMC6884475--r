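// Closed-loop driver-in-the-loop trial simulation: kinematic bicycle
// vehicle, piecewise straight/arc course projection, two-level steering
// controller with Ornstein-Uhlenbeck sensory noise and a command delay
// line. Mirrors the R reference path (make_driver_controller +
// simulate_trial's R loop) operation for operation, including the RNG draw
// order, so the two can be compared exactly at zero noise.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double wrapa(double a) { return std::atan2(std::sin(a), std::cos(a)); }

struct Proj {
  double s_proj, dev, dist, heading;
};

// Nearest point on segment i to (px, py); deviation positive = left of
// centerline in the direction of travel.
static Proj project_segment(int i,
                            const LogicalVector& is_arc,
                            const NumericVector& seg_len,
                            const NumericVector& seg_curv,
                            const NumericVector& seg_s0,
                            const NumericVector& seg_x0,
                            const NumericVector& seg_y0,
                            const NumericVector& seg_h0,
                            double px, double py) {
  Proj p;
  double u, fx, fy, h;
  if (!is_arc[i]) {
    double c = std::cos(seg_h0[i]), s = std::sin(seg_h0[i]);
    u = (px - seg_x0[i]) * c + (py - seg_y0[i]) * s;
    u = clampd(u, 0.0, seg_len[i]);
    fx = seg_x0[i] + u * c;
    fy = seg_y0[i] + u * s;
    h = seg_h0[i];
  } else {
    double k = seg_curv[i];
    double cx = seg_x0[i] - std::sin(seg_h0[i]) / k;
    double cy = seg_y0[i] + std::cos(seg_h0[i]) / k;
    double phi0 = std::atan2(seg_y0[i] - cy, seg_x0[i] - cx);
    double phi = std::atan2(py - cy, px - cx);
    u = wrapa(phi - phi0) / k;
    u = clampd(u, 0.0, seg_len[i]);
    h = seg_h0[i] + k * u;
    fx = cx + std::cos(phi0 + k * u) / std::fabs(k);
    fy = cy + std::sin(phi0 + k * u) / std::fabs(k);
  }
  p.s_proj = seg_s0[i] + u;
  p.dev = -std::sin(h) * (px - fx) + std::cos(h) * (py - fy);
  p.dist = std::sqrt((px - fx) * (px - fx) + (py - fy) * (py - fy));
  p.heading = h;
  return p;
}

// [[Rcpp::export]]
NumericMatrix sim_trial_cpp(LogicalVector is_arc, NumericVector seg_len,
                            NumericVector seg_curv, NumericVector seg_s0,
                            NumericVector seg_x0, NumericVector seg_y0,
                            NumericVector seg_h0, double total_length,
                            double lane_width,
                            double wheelbase, double steering_ratio,
                            double sw_max, double sw_rate_max,
                            double k_ant, double k_comp, double k_head,
                            double preview_time, double reaction_delay,
                            double sigma_visual, double sigma_audio,
                            double w_audio,
                            double sigma_curv, double sigma_heading,
                            double sigma_motor, double noise_tau,
                            double tau_ant, double tau_motor,
                            double enc_base, double enc_gain,
                            double enc_floor, double enc_ceiling,
                            int condition, int n_steps, double dt,
                            double speed) {
  int n_seg = is_arc.size();
  NumericMatrix out(n_steps, 7);
  colnames(out) = CharacterVector::create("t", "x", "y", "s_proj",
                                          "deviation", "sw_angle", "heading");
  RNGScope scope;

  double rho = std::exp(-dt / noise_tau);
  double q = std::sqrt(1.0 - rho * rho);
  double rho_m = std::exp(-dt / tau_motor);
  double q_m = std::sqrt(1.0 - rho_m * rho_m);
  double lag_ant = 1.0 - std::exp(-dt / tau_ant);
  double ou_vis = R::rnorm(0.0, 1.0) * sigma_visual;
  double ou_aud = R::rnorm(0.0, 1.0) * sigma_audio;
  double ou_curv = R::rnorm(0.0, 1.0) * sigma_curv;
  double ou_head = R::rnorm(0.0, 1.0) * sigma_heading;
  double ou_motor = R::rnorm(0.0, 1.0) * sigma_motor;
  double ff_state = 0.0;

  int delay_n = (int)std::lround(reaction_delay / dt);
  std::vector<double> buffer(std::max(delay_n, 1), 0.0);
  int head_i = 0;

  double x = 0.0, y = 0.0, heading = 0.0, sw = 0.0;
  int idx = 0;       // current segment of the projection
  int idx_ahead = 0; // segment of the preview point
  bool off_road = false;
  double sanity = 3.0 * lane_width;

  for (int i = 0; i < n_steps; ++i) {
    // --- project current position onto the centerline (local search) ---
    Proj best;
    bool have = false;
    int lo = std::max(idx - 1, 0), hi = std::min(idx + 2, n_seg - 1);
    for (int j = lo; j <= hi; ++j) {
      Proj p = project_segment(j, is_arc, seg_len, seg_curv, seg_s0,
                               seg_x0, seg_y0, seg_h0, x, y);
      if (!have || p.dist < best.dist - 1e-12 ||
          (std::fabs(p.dist - best.dist) <= 1e-12 && p.s_proj < best.s_proj)) {
        best = p;
        have = true;
        idx = j;
      }
    }
    if (std::fabs(best.dev) > sanity) off_road = true;

    // --- percept: previewed curvature, heading error, deviation estimate ---
    double s_ahead = best.s_proj + speed * preview_time;
    if (s_ahead > total_length) s_ahead = total_length;
    if (idx_ahead < idx) idx_ahead = idx;
    while (idx_ahead < n_seg - 1 &&
           s_ahead >= seg_s0[idx_ahead] + seg_len[idx_ahead]) {
      ++idx_ahead;
    }
    double far_true = seg_curv[idx_ahead];
    double herr_true = wrapa(heading - best.heading);

    ou_vis = rho * ou_vis + q * (R::rnorm(0.0, 1.0) * sigma_visual);
    ou_aud = rho * ou_aud + q * (R::rnorm(0.0, 1.0) * sigma_audio);
    ou_curv = rho * ou_curv + q * (R::rnorm(0.0, 1.0) * sigma_curv);
    ou_head = rho * ou_head + q * (R::rnorm(0.0, 1.0) * sigma_heading);
    ou_motor = rho_m * ou_motor + q_m * (R::rnorm(0.0, 1.0) * sigma_motor);

    double dev_est = 0.0;
    if (condition == 0) { // ND: visual near-road estimate
      dev_est = best.dev + ou_vis;
    } else if (condition == 2) { // SS: decode the binaural encoding
      double L = clampd(enc_base + enc_gain * best.dev, enc_floor, enc_ceiling);
      double Rr = clampd(enc_base - enc_gain * best.dev, enc_floor, enc_ceiling);
      double d = (L - Rr) / (2.0 * enc_gain);
      double lim = (enc_ceiling - enc_base) / enc_gain;
      bool sat = (L >= enc_ceiling) || (Rr >= enc_ceiling) ||
                 (L <= enc_floor) || (Rr <= enc_floor);
      if (sat) d = (d > 0 ? lim : (d < 0 ? -lim : 0.0));
      dev_est = w_audio * (d + ou_aud);
    } // VO: no deviation estimate, compensatory term 0

    double ff_target = k_ant * steering_ratio *
                       std::atan(wheelbase * (far_true + ou_curv));
    ff_state += lag_ant * (ff_target - ff_state);
    double raw = ff_state - k_comp * dev_est -
                 k_head * (herr_true + ou_head) + ou_motor;

    double cmd;
    if (delay_n == 0) {
      cmd = raw;
    } else {
      cmd = buffer[head_i];
      buffer[head_i] = raw;
      head_i = (head_i + 1 == delay_n) ? 0 : head_i + 1;
    }

    // --- steering slew/clamp, log, then advance the vehicle ---
    double dmax = sw_rate_max * dt;
    sw = sw + clampd(cmd - sw, -dmax, dmax);
    sw = clampd(sw, -sw_max, sw_max);

    out(i, 0) = i * dt;
    out(i, 1) = x;
    out(i, 2) = y;
    out(i, 3) = best.s_proj;
    out(i, 4) = best.dev;
    out(i, 5) = sw;
    out(i, 6) = heading;

    double delta = sw / steering_ratio;
    heading += speed * std::tan(delta) / wheelbase * dt;
    x += speed * std::cos(heading) * dt;
    y += speed * std::sin(heading) * dt;
  }
  out.attr("off_road") = off_road;
  return out;
}
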