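#include <Rcpp.h>
using namespace Rcpp;

// One direct-form-II-transposed pass over a column, generic order.
static inline void df2t_pass(const double *b, const double *a, int k,
                             const double *zi, double *col, int n, int step) {
  std::vector<double> z(k);
  int idx = (step > 0) ? 0 : n - 1;
  for (int i = 0; i < k; ++i) z[i] = zi[i] * col[idx];
  for (int t = 0; t < n; ++t, idx += step) {
    const double xt = col[idx];
    const double yt = b[0] * xt + z[0];
    for (int i = 0; i < k - 1; ++i)
      z[i] = b[i + 1] * xt + z[i + 1] - a[i + 1] * yt;
    z[k - 1] = b[k] * xt - a[k] * yt;
    col[idx] = yt;
  }
}

// Unrolled order-4 pass (the package's Butterworth sections), noticeably
// faster than the generic loop.
static inline void df2t_pass4(const double *b, const double *a,
                              const double *zi, double *col, int n,
                              int step) {
  const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4];
  const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4];
  int idx = (step > 0) ? 0 : n - 1;
  double z0 = zi[0] * col[idx], z1 = zi[1] * col[idx],
         z2 = zi[2] * col[idx], z3 = zi[3] * col[idx];
  for (int t = 0; t < n; ++t, idx += step) {
    const double xt = col[idx];
    const double yt = b0 * xt + z0;
    z0 = b1 * xt + z1 - a1 * yt;
    z1 = b2 * xt + z2 - a2 * yt;
    z2 = b3 * xt + z3 - a3 * yt;
    z3 = b4 * xt - a4 * yt;
    col[idx] = yt;
  }
}

// Zero-phase forward-backward IIR filtering, column-wise. Coefficients must
// be normalised (a[0] == 1, same length as b). zi is the steady-state filter
// state for a unit-level constant input; it is scaled by the first (last)
// sample of each column per pass, so a constant signal passes without
// start-up transients.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a, NumericMatrix x,
                           NumericVector zi) {
  const int n = x.nrow(), m = x.ncol(), k = a.size() - 1;
  NumericMatrix y = clone(x);
  for (int c = 0; c < m; ++c) {
    double *col = &y(0, c);
    if (k == 4) {
      df2t_pass4(b.begin(), a.begin(), zi.begin(), col, n, +1);
      df2t_pass4(b.begin(), a.begin(), zi.begin(), col, n, -1);
    } else {
      df2t_pass(b.begin(), a.begin(), k, zi.begin(), col, n, +1);
      df2t_pass(b.begin(), a.begin(), k, zi.begin(), col, n, -1);
    }
  }
  return y;
}

// In-place symmetric sweep (Beaton) of pivot k (1-based) on a square matrix.
// The caller owns A (freshly created) -- this mutates it without copying,
// which keeps the stepwise selection allocation-free.
// [[Rcpp::export]]
void cpp_sweep_inplace(NumericMatrix A, int k) {
  const int p = A.nrow();
  const int kk = k - 1;
  double *a = A.begin();
  const double d = a[kk * p + kk];
  std::vector<double> colk(p);
  for (int i = 0; i < p; ++i) colk[i] = a[kk * p + i];
  for (int j = 0; j < p; ++j) {
    const double f = a[j * p + kk] / d;
    if (f == 0.0) continue;
    double *cj = a + j * p;
    for (int i = 0; i < p; ++i) cj[i] -= colk[i] * f;
  }
  for (int i = 0; i < p; ++i) {
    a[kk * p + i] = colk[i] / d;
    a[i * p + kk] = colk[i] / d;
  }
  a[kk * p + kk] = -1.0 / d;
}
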