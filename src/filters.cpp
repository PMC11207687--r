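#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct-form-II-transposed biquad cascade over every row of a matrix.
// sos: n_sections x 6 (b0 b1 b2 a0 a1 a2), a0 assumed 1.
// [[Rcpp::export]]
arma::mat sos_filter_rows(const arma::mat& sos, const arma::mat& x) {
  arma::mat y = x;
  const arma::uword nsec = sos.n_rows, nc = y.n_rows, n = y.n_cols;
  // time-outer loop with per-row filter states: every column access is
  // contiguous, which keeps long multichannel recordings memory-friendly
  arma::vec z1(nc), z2(nc);
  for (arma::uword s = 0; s < nsec; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    z1.zeros();
    z2.zeros();
    double* yp = y.memptr();
    double* __restrict__ z1p = z1.memptr();
    double* __restrict__ z2p = z2.memptr();
    for (arma::uword c = 0; c < n; ++c) {
      double* __restrict__ col = yp + c * nc;
      for (arma::uword r = 0; r < nc; ++r) {
        const double in = col[r];
        const double out = b0 * in + z1p[r];
        z1p[r] = b1 * in - a1 * out + z2p[r];
        z2p[r] = b2 * in - a2 * out;
        col[r] = out;
      }
    }
  }
  return y;
}

// Zero-phase biquad-cascade filtering of every row: odd-reflection padding,
// forward pass, backward pass (reversed column order, fresh states), trim.
// Doing the whole thing here avoids several full-matrix copies in R.
// [[Rcpp::export]]
arma::mat sos_filtfilt_mat(const arma::mat& sos, const arma::mat& x,
                           const int pad) {
  const arma::uword nc = x.n_rows, n = x.n_cols, np = n + 2 * pad;
  arma::mat y(nc, np);
  for (int c = 0; c < pad; ++c) {
    y.col(c) = 2.0 * x.col(0) - x.col(pad - c);
  }
  y.cols(pad, pad + n - 1) = x;
  for (int c = 0; c < pad; ++c) {
    y.col(pad + n + c) = 2.0 * x.col(n - 1) - x.col(n - 2 - c);
  }
  const arma::uword nsec = sos.n_rows;
  arma::vec z1(nc), z2(nc);
  double* yp = y.memptr();
  double* __restrict__ z1p = z1.memptr();
  double* __restrict__ z2p = z2.memptr();
  for (int dir = 0; dir < 2; ++dir) {
    for (arma::uword s = 0; s < nsec; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      z1.zeros();
      z2.zeros();
      for (arma::uword ci = 0; ci < np; ++ci) {
        const arma::uword c = dir == 0 ? ci : np - 1 - ci;
        double* __restrict__ col = yp + c * nc;
        for (arma::uword r = 0; r < nc; ++r) {
          const double in = col[r];
          const double out = b0 * in + z1p[r];
          z1p[r] = b1 * in - a1 * out + z2p[r];
          z2p[r] = b2 * in - a2 * out;
          col[r] = out;
        }
      }
    }
  }
  return y.cols(pad, pad + n - 1);
}

// Stationary AR(1) recursion along each row: y[0] = innov[0],
// y[t] = rho * y[t-1] + innov[t].
// [[Rcpp::export]]
arma::mat ar1_filter_rows(const arma::mat& innov, const double rho) {
  arma::mat y = innov;
  const arma::uword nc = y.n_rows, n = y.n_cols;
  for (arma::uword r = 0; r < nc; ++r) {
    double prev = y(r, 0);
    for (arma::uword c = 1; c < n; ++c) {
      prev = rho * prev + y(r, c);
      y(r, c) = prev;
    }
  }
  return y;
}

// One synthesis pass for one (band, kappa) group of channels:
// out(r, c) = amp * cos(phi[c] + mu[r] + eps(r, c)), where
// eps = qtab-interpolated von Mises deviate of the Gaussian copula input g.
// qtab holds the von Mises quantile function on a uniform probability grid.
// [[Rcpp::export]]
arma::mat vm_band_signal(const arma::mat& g, const arma::vec& qtab,
                         const arma::rowvec& phi, const arma::vec& mu,
                         const double amp) {
  const arma::uword nr = g.n_rows, n = g.n_cols, m = qtab.n_elem;
  arma::mat out(nr, n);
  const double inv_sqrt2 = 0.7071067811865476;
  const double* gp = g.memptr();
  double* op = out.memptr();
  for (arma::uword c = 0; c < n; ++c) {
    const double ph = phi[c];
    for (arma::uword r = 0; r < nr; ++r) {
      const double u = 0.5 * std::erfc(-gp[c * nr + r] * inv_sqrt2);
      double x = u * (double)(m - 1);
      arma::uword i = (arma::uword)x;
      if (i >= m - 1) i = m - 2;
      const double w = x - (double)i;
      const double eps = qtab[i] + w * (qtab[i + 1] - qtab[i]);
      op[c * nr + r] = amp * std::cos(ph + mu[r] + eps);
    }
  }
  return out;
}
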