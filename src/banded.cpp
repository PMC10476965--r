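#include <Rcpp.h>
using namespace Rcpp;

// Symmetric banded matrices in lower compact storage: ab is (bw x n) with
// ab(d, j) = A(j + d, j) for d = 0..bw-1 (0-based); entries beyond the
// matrix edge are ignored. bw - 1 is the number of sub-diagonals.

// Banded Cholesky A = L L^T, L lower banded with the same bandwidth.
// Returns L in the same compact storage. O(n * bw^2). Column j of the
// compact storage holds A(j..j+bw-1, j), so the update of column j by an
// earlier column k walks both columns contiguously.
// [[Rcpp::export]]
NumericMatrix band_chol_cpp(NumericMatrix ab) {
  const int bw = ab.nrow(), n = ab.ncol();
  NumericMatrix L(clone(ab));
  double *Lp = REAL(L);
  for (int j = 0; j < n; ++j) {
    double *colj = Lp + (R_xlen_t)bw * j;
    // subtract the contributions of columns k in [j-bw+1, j-1]:
    // L(i, j) -= L(i, k) * L(j, k) for i = j .. min(k + bw - 1, n - 1)
    int k0 = std::max(0, j - bw + 1);
    for (int k = k0; k < j; ++k) {
      const double *colk = Lp + (R_xlen_t)bw * k;
      double ljk = colk[j - k];
      if (ljk == 0.0) continue;
      int imax = std::min(k + bw - 1, n - 1);
      const double *src = colk + (j - k);
      for (int i = j; i <= imax; ++i) colj[i - j] -= src[i - j] * ljk;
    }
    double s = colj[0];
    if (s <= 0.0) stop("banded matrix is not positive definite (pivot %d)", j + 1);
    double ljj = std::sqrt(s);
    colj[0] = ljj;
    int rmax = std::min(bw - 1, n - 1 - j);
    for (int r = 1; r <= rmax; ++r) colj[r] /= ljj;
  }
  return L;
}

// Solve A x = b given the banded Cholesky factor L: forward then backward
// substitution. b may have several columns.
// [[Rcpp::export]]
NumericMatrix band_chol_solve_cpp(NumericMatrix L, NumericMatrix b) {
  const int bw = L.nrow(), n = L.ncol(), m = b.ncol();
  if (b.nrow() != n) stop("rhs dimension mismatch");
  NumericMatrix x(clone(b));
  for (int c = 0; c < m; ++c) {
    // L y = b
    for (int i = 0; i < n; ++i) {
      double s = x(i, c);
      int k0 = std::max(0, i - bw + 1);
      for (int k = k0; k < i; ++k) s -= L(i - k, k) * x(k, c);
      x(i, c) = s / L(0, i);
    }
    // L^T x = y
    for (int i = n - 1; i >= 0; --i) {
      double s = x(i, c);
      int kmax = std::min(n - 1, i + bw - 1);
      for (int k = i + 1; k <= kmax; ++k) s -= L(k - i, i) * x(k, c);
      x(i, c) = s / L(0, i);
    }
  }
  return x;
}

// Diagonal of A^{-1} from the banded Cholesky factor, by the Takahashi
// (Erisman-Tinney) recurrence restricted to the band; exact for banded A
// because the recurrence closes on the band pattern. O(n * bw^2).
// [[Rcpp::export]]
NumericVector band_inv_diag_cpp(NumericMatrix L) {
  const int bw = L.nrow(), n = L.ncol();
  NumericMatrix Z(bw, n); // Z(d, j) = (A^{-1})(j + d, j), band only
  double *Zp = REAL(Z);
  const double *Lp = REAL(L);
  for (int j = n - 1; j >= 0; --j) {
    const double *colLj = Lp + (R_xlen_t)bw * j;
    const double ljj = colLj[0];
    const int imax = std::min(n - 1, j + bw - 1);
    for (int i = imax; i >= j; --i) {
      double s = 0.0;
      for (int k = j + 1; k <= imax; ++k) {
        const double lkj = colLj[k - j] / ljj; // unit-lower factor entry
        // Z(i, k): i and k both in (j, j+bw); |i-k| < bw so inside the band
        const double zik = (i >= k) ? Zp[(i - k) + (R_xlen_t)bw * k]
                                    : Zp[(k - i) + (R_xlen_t)bw * i];
        s += lkj * zik;
      }
      Zp[(i - j) + (R_xlen_t)bw * j] = (i == j) ? 1.0 / (ljj * ljj) - s : -s;
    }
  }
  NumericVector d(n);
  for (int j = 0; j < n; ++j) d[j] = Zp[(R_xlen_t)bw * j];
  return d;
}

// Build the banded Gaussian-likelihood Hessian block of the decoder:
//   H(a, b) += scale * dt * sum_t w(t) * kd(t - a) * kd(t - b)
// for |a - b| < bw, where kd is the cell's discretized membrane filter
// (length K) and w(t) the summed conditional intensity over that cell's
// trials. Accumulates into H (bw x n compact lower storage). O(n * K^2).
// [[Rcpp::export]]
void band_glm_hessian_acc_cpp(NumericMatrix H, NumericVector w,
                              NumericVector kd, double scale, double dt) {
  const int bw = H.nrow(), n = H.ncol(), K = kd.size();
  double *Hp = REAL(H);
  const double *wp = REAL(w), *kp = REAL(kd);
  const double c = scale * dt;
  std::vector<double> q(K);
  // diagonal d: H(a + d, a) = c * sum_u kd(u) kd(u + d) w(a + d + u)
  for (int d = 0; d < std::min(bw, K); ++d) {
    const int m = K - d;          // kernel length for this diagonal
    for (int u = 0; u < m; ++u) q[u] = c * kp[u] * kp[u + d];
    for (int a = 0; a + d < n; ++a) {
      const double *ww = wp + a + d;
      const int umax = std::min(m, n - a - d);
      double s = 0.0;
      for (int u = 0; u < umax; ++u) s += q[u] * ww[u];
      Hp[d + (R_xlen_t)bw * a] += s;
    }
  }
}

// Correlation of a signal with a causal kernel:
//   out(a) = sum_{u=0}^{K-1} kd(u) * x(a + u)
// (adjoint of the causal convolution); used for decoder gradients.
// [[Rcpp::export]]
NumericVector kernel_corr_cpp(NumericVector x, NumericVector kd) {
  const int n = x.size(), K = kd.size();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double s = 0.0;
    int umax = std::min(K - 1, n - 1 - a);
    for (int u = 0; u <= umax; ++u) s += kd[u] * x[a + u];
    out[a] = s;
  }
  return out;
}

// Causal convolution out(t) = sum_{u=0}^{min(t,K-1)} kd(u) * x(t - u).
// [[Rcpp::export]]
NumericVector causal_conv_cpp(NumericVector x, NumericVector kd) {
  const int n = x.size(), K = kd.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    int umax = std::min(K - 1, t);
    for (int u = 0; u <= umax; ++u) s += kd[u] * x[t - u];
    out[t] = s;
  }
  return out;
}
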