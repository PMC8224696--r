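#include <Rcpp.h>
using namespace Rcpp;

// Confined-diffusion substep walk. u and phi hold the pre-drawn Rayleigh
// step lengths and headings for all substeps ((N-1) * n_sub of them, drawn
// in R so the RNG stream stays reproducible). A proposed substep is accepted
// only if it stays strictly inside the circle of radius rc centred on the
// start position (the origin); otherwise the particle stays in place for
// that substep. Returns the N-1 recorded per-step positions.
// [[Rcpp::export]]
NumericMatrix cd_walk(NumericVector u, NumericVector phi, double rc, int n_sub) {
  const int total = u.size();
  const int steps = total / n_sub;
  NumericMatrix out(steps, 2);
  const double rc2 = rc * rc;
  double x = 0.0, y = 0.0;
  int k = 0;
  for (int i = 0; i < steps; ++i) {
    for (int j = 0; j < n_sub; ++j, ++k) {
      const double px = x + u[k] * std::cos(phi[k]);
      const double py = y + u[k] * std::sin(phi[k]);
      if (px * px + py * py < rc2) {
        x = px;
        y = py;
      }
    }
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}
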