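#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// median of a scratch vector (modified in place)
static double med_inplace(std::vector<double> &v) {
  const std::size_t n = v.size();
  if (n == 0) return NA_REAL;
  const std::size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

//' @title Moving median and MAD over a centered sample window
//' @description For each sample, the median and the (unscaled) median
//'   absolute deviation of the finite values inside a centered window of
//'   `window` samples (window/2 before, window/2 - 1 after; shrunk at the
//'   series edges). Missing values are skipped when forming the window
//'   statistics and get NA statistics only if their whole window is missing.
//' @noRd
// [[Rcpp::export(name = ".cpp_moving_median_mad")]]
NumericMatrix cpp_moving_median_mad(NumericVector x, int window) {
  const int n = x.size();
  if (window < 2) stop("window must be >= 2");
  const int before = window / 2;
  const int after = window - before - 1;
  NumericMatrix out(n, 2);
  std::vector<double> buf, dev;
  buf.reserve(window);
  dev.reserve(window);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - before);
    const int hi = std::min(n - 1, i + after);
    buf.clear();
    for (int j = lo; j <= hi; ++j)
      if (R_finite(x[j])) buf.push_back(x[j]);
    if (buf.empty()) {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
      continue;
    }
    dev = buf;  // med_inplace scrambles its argument
    const double m = med_inplace(dev);
    out(i, 0) = m;
    dev.clear();
    for (std::size_t j = 0; j < buf.size(); ++j)
      dev.push_back(std::fabs(buf[j] - m));
    out(i, 1) = med_inplace(dev);
  }
  return out;
}

// Stationary AR(1) noise (mean 0, stationary sd `sd`), R RNG.
// [[Rcpp::export(name = ".cpp_ar1")]]
NumericVector cpp_ar1(int n, double sd, double phi) {
  NumericVector out(n);
  if (n == 0) return out;
  const double eps = sd * std::sqrt(1.0 - phi * phi);
  double state = 0.0;
  for (int i = 0; i < n; ++i) {
    state = phi * state + eps * R::norm_rand();
    out[i] = state;
  }
  return out;
}

// Bounded 2D drift--diffusion walk with exponential repulsion from one
// point.  Used by the synthetic cohort for the search-task trajectory.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".cpp_fishing_walk")]]
List cpp_fishing_walk(int n, double dt, double x0, double z0,
                      double half_width, double depth,
                      double spider_x, double spider_z,
                      double repulsion, double repulse_scale,
                      double attract_k, double vel_tau,
                      double noise_sd, double retarget_rate) {
  NumericVector x(n), z(n), vx(n), vz(n);
  double px = x0, pz = z0, ux = 0.0, uz = 0.0;
  double wx = 0.0, wz = depth * 0.5;
  const double margin = 0.05;
  const double sq = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    if (R::runif(0.0, 1.0) < retarget_rate * dt) {
      wx = R::runif(-half_width + 0.3, half_width - 0.3);
      wz = R::runif(0.3, depth - 0.3);
    }
    double dxs = px - spider_x, dzs = pz - spider_z;
    double d = std::sqrt(dxs * dxs + dzs * dzs);
    if (d < 0.1) d = 0.1;
    const double f = repulsion * std::exp(-d / repulse_scale);
    double ax = attract_k * (wx - px) + f * dxs / d - ux / vel_tau +
                noise_sd * R::norm_rand() / sq;
    double az = attract_k * (wz - pz) + f * dzs / d - uz / vel_tau +
                noise_sd * R::norm_rand() / sq;
    ux += ax * dt;
    uz += az * dt;
    // walking-speed cap
    double sp = std::sqrt(ux * ux + uz * uz);
    if (sp > 1.4) { ux *= 1.4 / sp; uz *= 1.4 / sp; }
    px += ux * dt;
    pz += uz * dt;
    if (px < -half_width + margin) { px = -half_width + margin; ux = std::fabs(ux); }
    if (px > half_width - margin) { px = half_width - margin; ux = -std::fabs(ux); }
    if (pz < margin) { pz = margin; uz = std::fabs(uz); }
    if (pz > depth - margin) { pz = depth - margin; uz = -std::fabs(uz); }
    x[i] = px; z[i] = pz; vx[i] = ux; vz[i] = uz;
  }
  return List::create(_["x"] = x, _["z"] = z, _["vx"] = vx, _["vz"] = vz);
}

// 1D approach walk with proximity-dependent hesitation.  Progress s runs
// from 0 to dist; instantaneous speed is
//   v = base_speed * exp(-(h0 + h1 * frac^2)) * exp(ou)
// where frac = s/dist and ou is an Ornstein--Uhlenbeck log-speed
// fluctuation.  h0, h1 already include the latent-aversion scaling.
// Returns the progress trace (one value per dt step, last value >= dist).
// [[Rcpp::export(name = ".cpp_touch_walk")]]
NumericVector cpp_touch_walk(double dt, double dist, double base_speed,
                             double h0, double h1,
                             double noise_sd, double noise_tau, int max_n) {
  std::vector<double> s;
  s.reserve(2048);
  double prog = 0.0, ou = 0.0;
  const double sq = std::sqrt(dt);
  int i = 0;
  while (prog < dist && i < max_n) {
    ou += (-ou / noise_tau) * dt + noise_sd * sq * R::norm_rand();
    const double frac = prog / dist;
    double v = base_speed * std::exp(-(h0 + h1 * frac * frac) + ou);
    if (v < 0.005) v = 0.005;
    prog += v * dt;
    s.push_back(prog);
    ++i;
  }
  if (s.empty() || s.back() < dist) s.push_back(dist);
  return wrap(s);
}
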