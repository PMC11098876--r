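#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Universal back-projection onto a regular voxel grid.
// b: n_sensors x n_samples matrix of the back-projection term
//    b(t) = 2 p(t) - 2 t dp/dt, sampled on the acquisition time axis.
// weights: per-sensor solid-angle fraction (sums to 1 for uniform weighting).
// Flight times are looked up by linear interpolation in sample space; a voxel
// whose flight time falls outside the recorded window receives zero from that
// sensor (the number of such lookups is returned).
// [[Rcpp::export]]
List ubp_backproject_cpp(NumericMatrix b, NumericMatrix sensors,
                         NumericVector weights,
                         NumericVector xs, NumericVector ys, NumericVector zs,
                         double fs, double offset_samples, double c_mps) {
  const int ns = sensors.nrow();
  const int nt = b.ncol();
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const double c_mm = c_mps * 1000.0;
  NumericVector vol((size_t)nx * ny * nz);
  double* v = REAL(vol);
  const double* bb = REAL(b);
  double n_outside = 0.0;

  // cache sensor coords/weights in flat arrays
  std::vector<double> sxv(ns), syv(ns), szv(ns), wv(ns);
  for (int s = 0; s < ns; ++s) {
    sxv[s] = sensors(s, 0); syv[s] = sensors(s, 1); szv[s] = sensors(s, 2);
    wv[s] = weights[s];
  }

  size_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double z = zs[iz];
    for (int iy = 0; iy < ny; ++iy) {
      const double y = ys[iy];
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double x = xs[ix];
        double acc = 0.0;
        for (int s = 0; s < ns; ++s) {
          const double dx = x - sxv[s], dy = y - syv[s], dz = z - szv[s];
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          const double u = r / c_mm * fs - offset_samples;  // 0-based sample
          if (u < 0.0 || u > nt - 1.0) { n_outside += 1.0; continue; }
          const int k = (u >= nt - 1.0) ? nt - 2 : (int)u;
          const double f = u - k;
          const double val = (1.0 - f) * bb[s + (size_t)k * ns] +
                             f * bb[s + (size_t)(k + 1) * ns];
          acc += wv[s] * val;
        }
        v[idx] = acc;
      }
    }
  }
  // volume is returned with x fastest, then y, then z (dim = c(nx, ny, nz))
  return List::create(_["values"] = vol, _["n_outside"] = n_outside);
}
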