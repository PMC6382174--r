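#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of coupled stochastic Rossler oscillators on a graph.
// State per oscillator: (x, y, z); coupling acts on the x-equation through
// the Laplacian coefficients; noise d*eta enters the y-equation. After the
// burn-in, the y component is recorded every `record_every`-th step until
// n_points samples are stored. Uses R's RNG, so set.seed() governs
// reproducibility.
// [[Rcpp::export]]
NumericMatrix rossler_euler(NumericMatrix L, NumericVector w, double a,
                            double b, double c, double d, double sigma,
                            double dt, int n_points, int burn_in,
                            double noise_scale, int record_every) {
  const int n = L.nrow();
  NumericVector x = runif(n, -1.0, 1.0);
  NumericVector y = runif(n, -1.0, 1.0);
  NumericVector z = runif(n, -1.0, 1.0);
  NumericMatrix out(n_points, n);
  std::vector<double> cx(n);
  const long total = (long)burn_in + (long)n_points * record_every;

  // sparse representation of the Laplacian (structural graphs are sparse)
  std::vector<double> diag(n);
  std::vector<std::vector<int> > nb(n);
  std::vector<std::vector<double> > nbw(n);
  for (int i = 0; i < n; ++i) {
    diag[i] = L(i, i);
    for (int h = 0; h < n; ++h) {
      if (h != i && L(i, h) != 0.0) {
        nb[i].push_back(h);
        nbw[i].push_back(L(i, h));
      }
    }
  }

  for (long t = 0; t < total; ++t) {
    for (int i = 0; i < n; ++i) {
      double s = diag[i] * x[i];
      const std::vector<int>& nbi = nb[i];
      const std::vector<double>& nbwi = nbw[i];
      for (size_t k = 0; k < nbi.size(); ++k) s += nbwi[k] * x[nbi[k]];
      cx[i] = s;
    }
    NumericVector eta = rnorm(n);
    for (int i = 0; i < n; ++i) {
      const double dx = -w[i] * y[i] - z[i] - sigma * cx[i];
      const double dy = w[i] * x[i] + a * y[i];
      const double dz = b + (x[i] - c) * z[i];
      x[i] += dt * dx;
      y[i] += dt * dy + d * noise_scale * eta[i];
      z[i] += dt * dz;
      if (std::abs(x[i]) > 1e6 || std::abs(y[i]) > 1e6 || std::abs(z[i]) > 1e6) {
        stop("oscillator state diverged (|state| > 1e6) at step %d",
             (int)(t + 1));
      }
    }
    if (t >= burn_in && (t - burn_in) % record_every == record_every - 1) {
      const long row = (t - burn_in) / record_every;
      for (int i = 0; i < n; ++i) out(row, i) = y[i];
    }
  }
  return out;
}
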