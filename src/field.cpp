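// Attenuated Rayleigh-Sommerfeld integral over a discretized spherical cap.
#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// [[Rcpp::export]]
ComplexVector rsPressureCpp(NumericMatrix points, NumericMatrix patches,
                            double k, double atten, double min_dist) {
  const int n = points.nrow(), m = patches.nrow();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double re = 0.0, im = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - patches(j, 0);
      const double dy = py - patches(j, 1);
      const double dz = pz - patches(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < min_dist)
        stop("degenerate evaluation: field point within a cap patch");
      const double amp = std::exp(-atten * d) / d * patches(j, 3);
      re += amp * std::cos(k * d);
      im += amp * std::sin(k * d);
    }
    out[i] = Rcomplex{re, im};
  }
  return out;
}
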