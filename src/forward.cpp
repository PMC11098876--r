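#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate N-wave contributions from a set of uniform spherical absorbers
// at a set of sensor positions.  Units: positions mm, c in m/s, fs in Hz.
// The N-wave of a uniform sphere (radius a, initial pressure p0) observed at
// distance r is p(t) = p0 * (r - c t) / (2 r) for |r - c t| <= a, else 0.
// Sample k (0-based) is recorded at t = (offset + k) / fs.
// [[Rcpp::export]]
NumericMatrix nwave_accumulate_cpp(NumericMatrix sensors, NumericMatrix centers,
                                   NumericVector radius_mm, NumericVector p0,
                                   double fs, int n_samples, double offset_samples,
                                   double c_mps) {
  const int ns = sensors.nrow();
  const int na = centers.nrow();
  const double c_mm = c_mps * 1000.0;  // mm per second
  NumericMatrix out(ns, n_samples);
  double* o = REAL(out);
  for (int s = 0; s < ns; ++s) {
    const double sx = sensors(s, 0), sy = sensors(s, 1), sz = sensors(s, 2);
    for (int j = 0; j < na; ++j) {
      const double dx = sx - centers(j, 0);
      const double dy = sy - centers(j, 1);
      const double dz = sz - centers(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double a = radius_mm[j];
      if (r <= a)
        stop("sensor %d lies inside absorber %d (distance %.3f mm <= radius %.3f mm)",
             s + 1, j + 1, r, a);
      // support window in (0-based, fractional) sample units; the 1e-9
      // guard keeps edge samples consistently included when the window
      // boundary falls exactly on the sample grid
      const double u0 = (r - a) / c_mm * fs - offset_samples;
      const double u1 = (r + a) / c_mm * fs - offset_samples;
      int k0 = (int)std::ceil(u0 - 1e-9);
      int k1 = (int)std::floor(u1 + 1e-9);
      if (k0 < 0) k0 = 0;
      if (k1 > n_samples - 1) k1 = n_samples - 1;
      const double amp = p0[j] / (2.0 * r);
      for (int k = k0; k <= k1; ++k) {
        const double ct = c_mm * (offset_samples + k) / fs;
        o[s + (size_t)k * ns] += amp * (r - ct);
      }
    }
  }
  return out;
}
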