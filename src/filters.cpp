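#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Running median over a centred window of `w` samples.
// Edge policy: the window is truncated (shrunk one-sided) at the trace ends.
// Even windows (and even truncated windows) use the midpoint of the two
// central order statistics.
// [[Rcpp::export(name = ".run_median_cpp")]]
NumericVector run_median_cpp(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1) stop("window must contain at least one sample");
  if (w > n) stop("median window (%d samples) longer than trace (%d samples)", w, n);
  const int hl = (w - 1) / 2;      // samples to the left of centre
  const int hr = w - 1 - hl;       // samples to the right (>= hl)
  NumericVector out(n);
  std::vector<double> buf;         // kept sorted
  buf.reserve(w + 1);
  int l = 0, r = -1;               // current window [l, r]
  for (int i = 0; i < n; ++i) {
    const int nl = std::max(0, i - hl);
    const int nr = std::min(n - 1, i + hr);
    while (r < nr) {               // admit entering samples on the right
      ++r;
      buf.insert(std::lower_bound(buf.begin(), buf.end(), x[r]), x[r]);
    }
    while (l < nl) {               // evict samples leaving on the left
      buf.erase(std::lower_bound(buf.begin(), buf.end(), x[l]));
      ++l;
    }
    const int m = (int) buf.size();
    out[i] = (m % 2 == 1) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
  }
  return out;
}

// 1-D total variation denoising by majorization-minimization "iterative
// clipping" on the dual:  minimize 1/2 ||y - x||^2 + lambda * sum |diff(x)|.
// x = y - D'z with the dual variable z clipped to [-lambda, lambda]; step
// 1/alpha with alpha = 4 >= max eigenvalue of D D'.  With `iters` small the
// result is an under-converged edge-preserving smoother (the intended
// pipeline use); with `iters` large and tol > 0 it converges to the exact
// TV proximal operator.
// [[Rcpp::export(name = ".tvd_clip_cpp")]]
NumericVector tvd_clip_cpp(NumericVector y, double lambda, int iters, double tol) {
  const int n = y.size();
  NumericVector x = clone(y);
  if (n < 2 || lambda <= 0.0 || iters < 1) return x;
  std::vector<double> z(n - 1, 0.0);
  for (int it = 0; it < iters; ++it) {
    // z = clip(z + Dx/4, lambda)
    for (int i = 0; i < n - 1; ++i) {
      double zi = z[i] + 0.25 * (x[i + 1] - x[i]);
      if (zi > lambda) zi = lambda; else if (zi < -lambda) zi = -lambda;
      z[i] = zi;
    }
    // x = y - D'z, tracking the largest per-sample change
    double d = 0.0, xi;
    xi = y[0] + z[0];
    d = std::max(d, std::fabs(xi - x[0])); x[0] = xi;
    for (int i = 1; i < n - 1; ++i) {
      xi = y[i] - z[i - 1] + z[i];
      d = std::max(d, std::fabs(xi - x[i])); x[i] = xi;
    }
    xi = y[n - 1] - z[n - 2];
    d = std::max(d, std::fabs(xi - x[n - 1])); x[n - 1] = xi;
    if (tol > 0.0 && d < tol) break;
  }
  return x;
}
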