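#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Monte-Carlo PGSE signal for spins diffusing inside a reflecting sphere.
//
// Walkers start uniformly inside the sphere, take Gaussian steps of
// sd sqrt(2 D dt) per axis, and are specularly folded back at the boundary
// (radial mirror: |p| -> 2R - |p|, exact to first order in the step length).
// The gradient is applied along z with rectangular lobes [0, delta) and
// [Delta, Delta + delta); the accumulated phase is
//   phi = gam_g * dt * ( sum_{t in lobe1} z_t - sum_{t in lobe2} z_t )
// and the signal is mean(cos phi).  gam_g is recovered by the caller from
// b = gam_g^2 delta^2 (Delta - delta/3).
//
// An own mt19937_64 stream keeps this oracle independent of R's RNG while
// remaining reproducible from the seed argument.
// [[Rcpp::export(name = ".mc_sphere_signal_cpp")]]
double mc_sphere_signal_cpp(double R, double D, double delta_small,
                            double delta_big, double gam_g,
                            int n_walkers, double dt, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);

  const double t_end = delta_big + delta_small;
  const int n_steps = static_cast<int>(std::ceil(t_end / dt));
  const double step_sd = std::sqrt(2.0 * D * dt);
  double cos_sum = 0.0;

  for (int w = 0; w < n_walkers; ++w) {
    // uniform start inside the sphere (rejection)
    double x, y, z;
    do {
      x = unif(rng) * R; y = unif(rng) * R; z = unif(rng) * R;
    } while (x * x + y * y + z * z > R * R);

    double phase = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      // gradient sign for this interval (midpoint rule on the lobes; the
      // caller snaps dt so lobe edges fall on the step grid)
      const double tm = (s + 0.5) * dt;
      double gsign = 0.0;
      if (tm < delta_small) gsign = 1.0;
      else if (tm >= delta_big && tm < t_end) gsign = -1.0;

      const double z_prev = z;
      x += step_sd * gauss(rng);
      y += step_sd * gauss(rng);
      z += step_sd * gauss(rng);
      double r = std::sqrt(x * x + y * y + z * z);
      if (r > R) {
        const double rr = (2.0 * R - r) / r;
        x *= rr; y *= rr; z *= rr;
      }
      // trapezoidal phase accumulation (second order in dt)
      if (gsign != 0.0) phase += gsign * gam_g * 0.5 * (z_prev + z) * dt;
    }
    cos_sum += std::cos(phase);
  }
  return cos_sum / n_walkers;
}
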