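#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-frame update of the agent-based colony model. Bees carry a binary
// activity state; the active->inactive probability rises linearly as body
// temperature falls below 24 C, with an additive imidacloprid offset below
// t_thresh. Active bees take Gaussian steps plus a drift toward the brood
// centre of mass proportional to air-temperature deficit; inactive bees
// only jitter. Body temperature equals the local thermal field: ambient
// plus Gaussian kernels at brood items and at every bee (self included),
// evaluated in thermal-camera coordinates through the true warp.
//
// Uses R's RNG (unif_rand / norm_rand) so a set.seed() in R makes the whole
// trajectory bitwise reproducible. Draw order per frame is fixed and does
// not depend on treatment arm: one uniform per bee (transition), then two
// normals per bee (movement), so matched seeds yield matched streams.

static inline void warp_pt(double x, double y, const double *w,
                           double &tx, double &ty) {
  // w = {sx, sy, ox, oy, amp, period, phase}
  tx = w[2] + w[0] * x + w[4] * std::sin(2.0 * M_PI * y / w[5] + w[6]);
  ty = w[3] + w[1] * y + w[4] * std::cos(2.0 * M_PI * x / w[5] + w[6]);
}

// [[Rcpp::export]]
List sim_loop_cpp(NumericVector x0, NumericVector y0, IntegerVector s0,
                  NumericVector t_air, LogicalVector emit,
                  double p_ai_base, double p_ai_slope, double delta_ai_imid,
                  int imidacloprid, double t_thresh, double p_ia_base,
                  double thermotaxis_gain, double step_scale_px,
                  double inactive_jitter_px,
                  double body_heat_c, double body_sigma_px,
                  double brood_heat_c, double brood_sigma_px,
                  NumericVector brood_tx, NumericVector brood_ty,
                  double brood_cx, double brood_cy,
                  NumericVector warp, NumericVector bounds) {
  const int n = x0.size();
  const int n_frames = t_air.size();
  const int n_brood = brood_tx.size();
  int n_emit = 0;
  for (int i = 0; i < n_frames; ++i) if (emit[i]) ++n_emit;

  NumericMatrix out_x(n_emit, n), out_y(n_emit, n), out_temp(n_emit, n),
      out_pai(n_emit, n);
  IntegerMatrix out_state(n_emit, n);

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<int> state(s0.begin(), s0.end());
  std::vector<double> tx(n), ty(n), tbody(n);
  const double *w = warp.begin();
  const double xmin = bounds[0], xmax = bounds[1], ymin = bounds[2],
               ymax = bounds[3];
  const double inv2_body = 1.0 / (2.0 * body_sigma_px * body_sigma_px);
  const double inv2_brood = 1.0 / (2.0 * brood_sigma_px * brood_sigma_px);

  int e = 0;
  for (int f = 0; f < n_frames; ++f) {
    const double ta = t_air[f];
    for (int i = 0; i < n; ++i) warp_pt(x[i], y[i], w, tx[i], ty[i]);
    const double cut_body = 16.0 * body_sigma_px * body_sigma_px;
    const double cut_brood = 16.0 * brood_sigma_px * brood_sigma_px;
    for (int i = 0; i < n; ++i) {
      double t = ta + body_heat_c;  // own kernel at distance zero
      for (int b = 0; b < n_brood; ++b) {
        const double dx = tx[i] - brood_tx[b], dy = ty[i] - brood_ty[b];
        const double d2 = dx * dx + dy * dy;
        if (d2 < cut_brood) t += brood_heat_c * std::exp(-d2 * inv2_brood);
      }
      tbody[i] = t;
    }
    for (int i = 0; i < n; ++i) {  // bee-bee kernels once per pair
      for (int j = i + 1; j < n; ++j) {
        const double dx = tx[i] - tx[j], dy = ty[i] - ty[j];
        const double d2 = dx * dx + dy * dy;
        if (d2 < cut_body) {
          const double k = body_heat_c * std::exp(-d2 * inv2_body);
          tbody[i] += k;
          tbody[j] += k;
        }
      }
    }
    if (emit[f]) {
      for (int i = 0; i < n; ++i) {
        out_x(e, i) = x[i];
        out_y(e, i) = y[i];
        out_temp(e, i) = tbody[i];
        out_state(e, i) = state[i];
        double p = p_ai_base + p_ai_slope * std::max(0.0, 24.0 - tbody[i]);
        if (imidacloprid && tbody[i] < t_thresh) p += delta_ai_imid;
        out_pai(e, i) = std::min(1.0, std::max(0.0, p));
      }
      ++e;
    }
    // movement t -> t+1 for bees active at t; jitter otherwise
    const double drift_mag = thermotaxis_gain * std::max(0.0, 24.0 - ta);
    for (int i = 0; i < n; ++i) {
      const double scale = state[i] ? step_scale_px : inactive_jitter_px;
      double dx = scale * norm_rand(), dy = scale * norm_rand();
      if (state[i] && drift_mag > 0.0) {
        const double vx = brood_cx - x[i], vy = brood_cy - y[i];
        const double d = std::sqrt(vx * vx + vy * vy);
        if (d > 1e-9) {
          dx += drift_mag * vx / d;
          dy += drift_mag * vy / d;
        }
      }
      x[i] = std::min(xmax, std::max(xmin, x[i] + dx));
      y[i] = std::min(ymax, std::max(ymin, y[i] + dy));
    }
    // state t -> t+1 from body temperature at t
    for (int i = 0; i < n; ++i) {
      const double u = unif_rand();
      if (state[i]) {
        double p = p_ai_base + p_ai_slope * std::max(0.0, 24.0 - tbody[i]);
        if (imidacloprid && tbody[i] < t_thresh) p += delta_ai_imid;
        p = std::min(1.0, std::max(0.0, p));
        if (u < p) state[i] = 0;
      } else {
        if (u < p_ia_base) state[i] = 1;
      }
    }
  }
  return List::create(_["x"] = out_x, _["y"] = out_y, _["temp"] = out_temp,
                      _["state"] = out_state, _["p_ai"] = out_pai);
}

// Fused per-frame pass over a segment's detections (sorted by frame):
// contact counts, distinct-partner adjacency and mean nest-mate distance.
// frame_off holds 0-based offsets of each frame's first row, with a final
// sentinel equal to the number of rows; bee is a 0-based bee index.
// [[Rcpp::export]]
List contact_pass_cpp(NumericVector x, NumericVector y,
                      IntegerVector frame_off, IntegerVector bee,
                      int n_bees, double thr_px) {
  NumericVector contact_n(n_bees), nm_sum(n_bees), nm_frames(n_bees);
  LogicalMatrix partner(n_bees, n_bees);
  const double thr2 = thr_px * thr_px;
  const int n_frames = frame_off.size() - 1;
  for (int f = 0; f < n_frames; ++f) {
    const int a = frame_off[f], b = frame_off[f + 1];
    const int nf = b - a;
    if (nf < 2) continue;
    for (int i = a; i < b; ++i) {
      double dsum = 0.0;
      int ncontact = 0;
      for (int j = a; j < b; ++j) {
        if (i == j) continue;
        const double dx = x[i] - x[j], dy = y[i] - y[j];
        const double d2 = dx * dx + dy * dy;
        dsum += std::sqrt(d2);
        if (d2 < thr2) {
          ++ncontact;
          partner(bee[i], bee[j]) = true;
        }
      }
      contact_n[bee[i]] += ncontact;
      nm_sum[bee[i]] += dsum / (nf - 1);
      nm_frames[bee[i]] += 1.0;
    }
  }
  return List::create(_["contact_n"] = contact_n, _["partner"] = partner,
                      _["nm_sum"] = nm_sum, _["nm_frames"] = nm_frames);
}
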