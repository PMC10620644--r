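#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama propagation on the (d, theta) plane under a
// sum-of-Gaussian-wells potential
//   U(d, theta) = -sum_k depth_k * exp(-[(d-cd)^2/(2 sd^2)
//                                        + (theta-ct)^2/(2 st^2)])
// with per-coordinate friction and reflecting walls. Noise is drawn from
// R's RNG so that set.seed() on the R side fixes trajectories exactly.
//
// basins: matrix with columns (center_d, center_theta, depth, sigma_d,
// sigma_theta), one row per well. One output frame is recorded every
// `substeps` integrator steps; frame 0 is the input state.

static inline void grad_u(const double d, const double th,
                          const NumericMatrix &basins,
                          double &gd, double &gth) {
  gd = 0.0;
  gth = 0.0;
  const int nb = basins.nrow();
  for (int k = 0; k < nb; ++k) {
    const double dx = d - basins(k, 0);
    const double dy = th - basins(k, 1);
    const double s2d = basins(k, 3) * basins(k, 3);
    const double s2t = basins(k, 4) * basins(k, 4);
    const double e = basins(k, 2) *
      std::exp(-(dx * dx / (2.0 * s2d) + dy * dy / (2.0 * s2t)));
    gd += e * dx / s2d;
    gth += e * dy / s2t;
  }
}

static inline double reflect(double x, const double lo, const double hi) {
  // fold back into [lo, hi]; loop handles rare multi-width excursions
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

// [[Rcpp::export]]
NumericMatrix langevin_segment_cpp(NumericVector x0, int n_frames,
                                   int substeps, double dt,
                                   NumericVector gamma, double kT,
                                   NumericMatrix basins,
                                   NumericVector d_walls,
                                   NumericVector theta_walls) {
  NumericMatrix out(n_frames + 1, 2);
  double d = x0[0], th = x0[1];
  d = reflect(d, d_walls[0], d_walls[1]);
  th = reflect(th, theta_walls[0], theta_walls[1]);
  out(0, 0) = d;
  out(0, 1) = th;
  const double nd = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma[0]) : 0.0;
  const double nt = (kT > 0.0) ? std::sqrt(2.0 * kT * dt / gamma[1]) : 0.0;
  double gd, gth;
  for (int f = 1; f <= n_frames; ++f) {
    for (int s = 0; s < substeps; ++s) {
      grad_u(d, th, basins, gd, gth);
      d += -gd * dt / gamma[0];
      th += -gth * dt / gamma[1];
      if (kT > 0.0) {
        d += nd * norm_rand();
        th += nt * norm_rand();
      }
      d = reflect(d, d_walls[0], d_walls[1]);
      th = reflect(th, theta_walls[0], theta_walls[1]);
    }
    out(f, 0) = d;
    out(f, 1) = th;
  }
  return out;
}
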