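#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orientation-averaged spectral density of a planar point set.
//
// For each rotation angle theta_k = 2*pi*k/n_theta the points (t_j, x_j) are
// projected onto the rotated axis, u_j = cos(theta) t_j + sin(theta) x_j,
// and S(f, theta) = |(1/N) sum_j exp(i f u_j)|^2.  The returned value per
// frequency is the mean over the n_theta angles.  This is the hot loop of
// the package (N * n_theta * n_freq trig evaluations), hence C++.
// [[Rcpp::export(name = ".sf_kernel")]]
NumericVector sf_kernel(NumericVector t, NumericVector x,
                        NumericVector freqs, int n_theta) {
  const int n = t.size();
  const int nf = freqs.size();
  if (x.size() != n) stop("t and x must have equal length");
  if (n_theta < 1) stop("n_theta must be >= 1");
  NumericVector out(nf);
  std::vector<double> u(n);
  for (int k = 0; k < n_theta; ++k) {
    const double th = 2.0 * M_PI * k / n_theta;
    const double c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < n; ++j) u[j] = c * t[j] + s * x[j];
    for (int q = 0; q < nf; ++q) {
      const double f = freqs[q];
      double sc = 0.0, ss = 0.0;
      for (int j = 0; j < n; ++j) {
        sc += std::cos(f * u[j]);
        ss += std::sin(f * u[j]);
      }
      sc /= n;
      ss /= n;
      out[q] += sc * sc + ss * ss;
    }
  }
  for (int q = 0; q < nf; ++q) out[q] /= n_theta;
  return out;
}
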