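#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Earliest intersection parameter s in [0,1] of segment p0 + s*(p1-p0) with the
// circle |p| = r centred at the origin, or -1 if the segment stays outside.
// The walk starts outside the disk and stops at first contact, so p0 is always
// outside (|p0| > r) except in the degenerate start-on-surface case.
static double segment_circle_hit(double x0, double y0, double x1, double y1,
                                 double r) {
  const double c0 = x0 * x0 + y0 * y0 - r * r;
  if (c0 <= 0.0) return 0.0;  // starting on/inside the surface
  const double dx = x1 - x0, dy = y1 - y0;
  const double a = dx * dx + dy * dy;
  if (a == 0.0) return -1.0;  // zero-length segment, point already tested
  const double b = 2.0 * (x0 * dx + y0 * dy);
  const double disc = b * b - 4.0 * a * c0;
  if (disc < 0.0) return -1.0;
  const double s = (-b - std::sqrt(disc)) / (2.0 * a);
  if (s >= 0.0 && s <= 1.0) return s;
  return -1.0;
}

// Simulate n finite-length persistent random walks from (x0, y0) searching for
// an absorbing disk of radius rtarg at the origin.  Explicit Euler-Maruyama:
// the displacement at each step uses the heading *before* the stochastic
// increment is applied.  Uses R's RNG so set.seed() governs reproducibility;
// trajectories consume draws sequentially.
//
// duration: per-trajectory growth time (min); the contour length simulated is
// min(v * duration, lmax).  record_every > 0 stores every k-th frame (plus the
// start and the final/contact frame) of position and heading.
// [[Rcpp::export]]
List prw_ensemble_cpp(int n, double v, double dtheta, double lmax,
                      double x0, double y0, double rtarg, double dt,
                      NumericVector init_angle, NumericVector duration,
                      int record_every) {
  LogicalVector contacted(n);
  NumericVector t_contact(n, NA_REAL), contact_x(n, NA_REAL),
      contact_y(n, NA_REAL), final_length(n), theta_final(n);

  const double sig = std::sqrt(2.0 * dtheta * dt);
  const double step = v * dt;
  const bool record = record_every > 0;

  std::vector<int> rec_id;
  std::vector<double> rec_t, rec_x, rec_y, rec_th;

  for (int i = 0; i < n; ++i) {
    double th = init_angle[i % init_angle.size()];
    double dur = duration[i % duration.size()];
    double t_cap = std::min(dur, lmax / v);
    int n_steps = (int)std::ceil(t_cap / dt - 1e-12);
    double x = x0, y = y0;
    bool hit = false;

    if (record) {
      rec_id.push_back(i + 1); rec_t.push_back(0.0);
      rec_x.push_back(x); rec_y.push_back(y); rec_th.push_back(th);
    }

    int k = 0;
    for (k = 0; k < n_steps; ++k) {
      const double xn = x + step * std::cos(th);
      const double yn = y + step * std::sin(th);
      const double s = segment_circle_hit(x, y, xn, yn, rtarg);
      if (s >= 0.0) {
        hit = true;
        contact_x[i] = x + s * (xn - x);
        contact_y[i] = y + s * (yn - y);
        t_contact[i] = (k + s) * dt;
        final_length[i] = (k + s) * step;
        x = contact_x[i]; y = contact_y[i];
        ++k;
        break;
      }
      x = xn; y = yn;
      th += sig * norm_rand();
      if (record && ((k + 1) % record_every == 0) && (k + 1 < n_steps)) {
        rec_id.push_back(i + 1); rec_t.push_back((k + 1) * dt);
        rec_x.push_back(x); rec_y.push_back(y); rec_th.push_back(th);
      }
    }
    contacted[i] = hit;
    theta_final[i] = th;
    if (!hit) final_length[i] = n_steps * step;
    if (record) {  // final (or contact) frame
      rec_id.push_back(i + 1);
      rec_t.push_back(hit ? t_contact[i] : n_steps * dt);
      rec_x.push_back(x); rec_y.push_back(y); rec_th.push_back(th);
    }
  }

  List out = List::create(
      _["contacted"] = contacted, _["t_contact"] = t_contact,
      _["contact_x"] = contact_x, _["contact_y"] = contact_y,
      _["final_length"] = final_length, _["theta_final"] = theta_final);
  if (record) {
    out["rec_id"] = IntegerVector(rec_id.begin(), rec_id.end());
    out["rec_t"] = NumericVector(rec_t.begin(), rec_t.end());
    out["rec_x"] = NumericVector(rec_x.begin(), rec_x.end());
    out["rec_y"] = NumericVector(rec_y.begin(), rec_y.end());
    out["rec_theta"] = NumericVector(rec_th.begin(), rec_th.end());
  }
  return out;
}

// Brownian walkers with absorbing disk, used as an independent Monte-Carlo
// check of the diffusive-limit survival PDE.  Absorption tested on the
// end-of-step position (dt must be small).
// [[Rcpp::export]]
NumericVector brownian_absorption_cpp(int n, double D, double x0, double y0,
                                      double rtarg, double dt, double t_max) {
  int n_steps = (int)std::ceil(t_max / dt - 1e-12);
  const double sig = std::sqrt(2.0 * D * dt);
  NumericVector t_hit(n, NA_REAL);
  const double r2 = rtarg * rtarg;
  for (int i = 0; i < n; ++i) {
    double x = x0, y = y0;
    for (int k = 0; k < n_steps; ++k) {
      x += sig * norm_rand();
      y += sig * norm_rand();
      if (x * x + y * y <= r2) {
        t_hit[i] = (k + 1) * dt;
        break;
      }
    }
  }
  return t_hit;
}
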