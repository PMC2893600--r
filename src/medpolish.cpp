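#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median with R's convention (mean of the two middle order statistics for
// even n); v is scratch and may be reordered
static double med(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Tukey median polish of one probe set (rows = probes, cols = samples),
// mirroring stats::medpolish: per iteration a row sweep then a column
// sweep, each followed by re-centering of the opposing effects; stop when
// the total absolute residual changes by less than eps (relative) or after
// maxiter iterations. Writes overall + column effects into expr.
static void polish_group(const double *x, int nr, int nc, int ldx,
                         int maxiter, double eps, double *expr) {
  std::vector<double> z((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      z[(size_t)j * nr + i] = x[(size_t)j * ldx + i];

  std::vector<double> r(nr, 0.0), c(nc, 0.0), scratch;
  double t = 0.0, oldsum = 0.0;

  for (int iter = 0; iter < maxiter; ++iter) {
    // row sweep
    for (int i = 0; i < nr; ++i) {
      scratch.resize(nc);
      for (int j = 0; j < nc; ++j) scratch[j] = z[(size_t)j * nr + i];
      double m = med(scratch);
      for (int j = 0; j < nc; ++j) z[(size_t)j * nr + i] -= m;
      r[i] += m;
    }
    scratch = c;
    double delta = med(scratch);
    for (int j = 0; j < nc; ++j) c[j] -= delta;
    t += delta;
    // column sweep
    for (int j = 0; j < nc; ++j) {
      scratch.assign(z.begin() + (size_t)j * nr, z.begin() + (size_t)(j + 1) * nr);
      double m = med(scratch);
      for (int i = 0; i < nr; ++i) z[(size_t)j * nr + i] -= m;
      c[j] += m;
    }
    scratch = r;
    delta = med(scratch);
    for (int i = 0; i < nr; ++i) r[i] -= delta;
    t += delta;

    double newsum = 0.0;
    for (size_t k = 0; k < z.size(); ++k) newsum += std::fabs(z[k]);
    if (newsum == 0.0 || std::fabs(newsum - oldsum) < eps * newsum) break;
    oldsum = newsum;
  }
  for (int j = 0; j < nc; ++j) expr[j] = t + c[j];
}

// [[Rcpp::export]]
NumericMatrix medpolish_groups(NumericMatrix x, IntegerVector group_sizes,
                               int maxiter = 10, double eps = 0.01) {
  const int nc = x.ncol();
  const int ng = group_sizes.size();
  const int nr = x.nrow();
  long total = 0;
  for (int g = 0; g < ng; ++g) {
    if (group_sizes[g] < 1) stop("group sizes must be >= 1");
    total += group_sizes[g];
  }
  if (total != nr) stop("group sizes do not sum to nrow(x)");

  NumericMatrix expr(ng, nc);
  const double *xp = REAL(x);
  int offset = 0;
  std::vector<double> row(nc);
  for (int g = 0; g < ng; ++g) {
    polish_group(xp + offset, group_sizes[g], nc, nr, maxiter, eps, &row[0]);
    for (int j = 0; j < nc; ++j) expr(g, j) = row[j];
    offset += group_sizes[g];
  }
  return expr;
}
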