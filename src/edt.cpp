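#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// One-dimensional squared distance transform along a sampled line with
// sample spacing h (Felzenszwalb & Huttenlocher, Theory of Computing 2012).
// f holds squared distances on input; d receives the lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * h;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; if (k < 0) break; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) { // no finite sites on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// Squared Euclidean distance transform of the background of a foreground
// mask, for arbitrary dimensionality, with per-axis sample spacing.
// mask: column-major array flattened; nonzero = foreground (distance 0).
// [[Rcpp::export]]
NumericVector edt_squared_cpp(NumericVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nd = dims.size();
  if (spacing.size() != nd) stop("spacing must have one entry per axis");
  R_xlen_t total = 1;
  for (int a = 0; a < nd; ++a) total *= dims[a];
  if (total != mask.size()) stop("mask length does not match dims");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(total);
  for (R_xlen_t i = 0; i < total; ++i) d[i] = (mask[i] != 0) ? 0.0 : INF;

  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int a = 1; a < nd; ++a) stride[a] = stride[a - 1] * dims[a - 1];

  for (int a = 0; a < nd; ++a) {
    const int n = dims[a];
    const R_xlen_t s = stride[a];
    std::vector<double> f(n), g(n);
    // enumerate all line starts: indices whose a-th coordinate is zero
    for (R_xlen_t idx = 0; idx < total; ++idx) {
      if ((idx / s) % n != 0) continue;
      for (int q = 0; q < n; ++q) f[q] = d[idx + (R_xlen_t)q * s];
      dt1d(f, g, spacing[a]);
      for (int q = 0; q < n; ++q) d[idx + (R_xlen_t)q * s] = g[q];
    }
  }

  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i) out[i] = d[i];
  out.attr("dim") = dims;
  return out;
}
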