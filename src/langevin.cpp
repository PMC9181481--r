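#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quintic smoothstep derivative d s / d t with s(t) = 6t^5 - 15t^4 + 10t^3.
static inline double smoothstep_deriv(double t) {
  return 30.0 * t * t * (t - 1.0) * (t - 1.0);
}

// dG/dz of the parametric interface potential (see R/potential.R).
static inline double pmf_grad(double z, double g_vac, double g_bulk,
                              double z_int, double w_int, double w_sw,
                              double well_depth) {
  double a = std::fabs(z);
  double lo = z_int - w_sw, hi = z_int + w_sw;
  double ds = 0.0;
  if (a > lo && a < hi) {
    double t = (hi - a) / (2.0 * w_sw);
    ds = -smoothstep_deriv(t) / (2.0 * w_sw);
    if (z < 0) ds = -ds;
  }
  double g = (g_bulk - g_vac) * ds;
  double w2 = w_int * w_int;
  double dm = z - z_int, dp = z + z_int;
  g += well_depth * (std::exp(-dm * dm / (2.0 * w2)) * dm +
                     std::exp(-dp * dp / (2.0 * w2)) * dp) / w2;
  return g;
}

// Euler-Maruyama overdamped Langevin chain on G(z) + k/2 (z - center)^2.
// `noise` supplies the standard-normal increments (generated R-side so
// reproducibility rests on R's RNG); one sample is recorded every
// `stride` steps.
// [[Rcpp::export]]
NumericVector langevin_chain(double z_start, double center, double k,
                             double dt, double diffusion, double rt,
                             int n_steps, int stride, NumericVector noise,
                             double g_vac, double g_bulk, double z_int,
                             double w_int, double w_sw, double well_depth,
                             double z_max) {
  if (noise.size() < n_steps)
    stop("noise vector shorter than n_steps");
  int n_out = (stride > 0) ? n_steps / stride : 0;
  NumericVector out(n_out);
  double z = z_start;
  double mob = diffusion / rt;
  double sn = std::sqrt(2.0 * diffusion * dt);
  int j = 0;
  for (int i = 0; i < n_steps; ++i) {
    double grad = pmf_grad(z, g_vac, g_bulk, z_int, w_int, w_sw, well_depth) +
      k * (z - center);
    z += -mob * grad * dt + sn * noise[i];
    if (std::fabs(z) > z_max + 1.0)
      stop("sampler instability: |z| exceeded z_max + 1 nm at step %d", i + 1);
    if ((i + 1) % stride == 0 && j < n_out)
      out[j++] = z;
  }
  return out;
}
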