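#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson step for the contour diffusion substep, applied along the
// rows of Q: solves (I - theta*L) X = (I + theta*L) Q column by column,
// where L is the tridiagonal Laplacian with bands lo (sub), dg (main),
// up (super), all of length n (lo[0] and up[n-1] are ignored/zero at
// no-flux boundaries).  Thomas algorithm; the elimination coefficients are
// computed once and reused for every column.
// [[Rcpp::export]]
NumericMatrix cn_solve_rows(NumericVector lo, NumericVector dg,
                            NumericVector up, double theta,
                            NumericMatrix Q) {
  const int n = dg.size();
  const int k = Q.ncol();
  if (Q.nrow() != n) stop("band length does not match matrix rows");

  // bands of A = I - theta*L
  std::vector<double> a(n), b(n), c(n);
  for (int i = 0; i < n; ++i) {
    a[i] = -theta * lo[i];
    b[i] = 1.0 - theta * dg[i];
    c[i] = -theta * up[i];
  }

  // Thomas forward-elimination factors
  std::vector<double> cp(n), m(n);
  m[0] = b[0];
  cp[0] = c[0] / m[0];
  for (int i = 1; i < n; ++i) {
    m[i] = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / m[i];
  }

  NumericMatrix X(n, k);
  std::vector<double> rhs(n), dp(n);
  for (int j = 0; j < k; ++j) {
    // rhs = (I + theta*L) q
    const double* q = &Q(0, j);
    rhs[0] = (1.0 + theta * dg[0]) * q[0] +
             (n > 1 ? theta * up[0] * q[1] : 0.0);
    for (int i = 1; i < n - 1; ++i) {
      rhs[i] = theta * lo[i] * q[i - 1] + (1.0 + theta * dg[i]) * q[i] +
               theta * up[i] * q[i + 1];
    }
    if (n > 1)
      rhs[n - 1] = theta * lo[n - 1] * q[n - 2] +
                   (1.0 + theta * dg[n - 1]) * q[n - 1];

    dp[0] = rhs[0] / m[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (rhs[i] - a[i] * dp[i - 1]) / m[i];
    X(n - 1, j) = dp[n - 1];
    for (int i = n - 2; i >= 0; --i)
      X(i, j) = dp[i] - cp[i] * X(i + 1, j);
  }
  return X;
}
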