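#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brute-force mean-first-passage oracle on the synthetic two-dimensional
// double well F(x, y) = h (x^2 - 1)^2 + ky/2 (y - c x)^2 (kBT units).
// Minima at (+-1, +-c), saddle at (0, 0) with barrier h. Overdamped BD with
// diagonal diffusion (Dx, Dy); a passage is first arrival at x >= x_abs.
// [[Rcpp::export]]
NumericVector cpp_dw2d_fpt(double h, double ky, double c, double Dx, double Dy,
                           double dt, int n_escapes, double max_steps,
                           double x_abs = 0.0) {
  NumericVector fpt(n_escapes);
  for (int i = 0; i < n_escapes; ++i) {
    double xx = -1.0, yy = -c;
    double s = 0;
    for (; s < max_steps; ++s) {
      double fx = -(4.0 * h * xx * (xx * xx - 1.0) - ky * c * (yy - c * xx));
      double fy = -ky * (yy - c * xx);
      xx += Dx * fx * dt + std::sqrt(2.0 * Dx * dt) * norm_rand();
      yy += Dy * fy * dt + std::sqrt(2.0 * Dy * dt) * norm_rand();
      if (xx >= x_abs) break;
    }
    fpt[i] = (s + 1) * dt;
    if ((i & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return fpt;
}

// 1-D harmonic walker first-passage times (used against a Smoluchowski
// mean-first-passage quadrature oracle): F(x) = k/2 x^2, start at x0,
// absorbing at x >= x_abs.
// [[Rcpp::export]]
NumericVector cpp_harmonic_fpt(double k, double D, double dt, double x0,
                               double x_abs, int n, double max_steps) {
  NumericVector fpt(n);
  for (int i = 0; i < n; ++i) {
    double xx = x0;
    double s = 0;
    for (; s < max_steps; ++s) {
      xx += -D * k * xx * dt + std::sqrt(2.0 * D * dt) * norm_rand();
      if (xx >= x_abs) break;
    }
    fpt[i] = (s + 1) * dt;
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return fpt;
}
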