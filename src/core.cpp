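// Compiled hot paths: patch extraction/normalization and the online
// subspace update. Both mirror the R reference semantics exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cut a binocular window pair into normalized 200-d patch vectors.
// idx: 100 x P matrix of 1-based linear indices into the window matrices.
// [[Rcpp::export]]
List patchify_core(const arma::mat& left, const arma::mat& right,
                   const arma::umat& idx) {
  const arma::uword ppx = idx.n_rows;   // 100 pixels per patch
  const arma::uword P = idx.n_cols;
  arma::mat X(2 * ppx, P);
  LogicalVector low(P);
  const double* L = left.memptr();
  const double* R = right.memptr();
  const double denom = (double)(ppx - 1);
  for (arma::uword j = 0; j < P; ++j) {
    double* col = X.colptr(j);
    long double sl = 0.0, sr = 0.0;   // exact for constant patches
    for (arma::uword i = 0; i < ppx; ++i) {
      const arma::uword k = idx(i, j) - 1;
      col[i] = L[k];
      col[ppx + i] = R[k];
      sl += col[i]; sr += col[ppx + i];
    }
    const double ml = (double)(sl / ppx), mr = (double)(sr / ppx);
    double vl = 0.0, vr = 0.0;
    for (arma::uword i = 0; i < ppx; ++i) {
      col[i] -= ml; vl += col[i] * col[i];
      col[ppx + i] -= mr; vr += col[ppx + i] * col[ppx + i];
    }
    double sdl = std::sqrt(vl / denom), sdr = std::sqrt(vr / denom);
    bool lowc = (sdl < 1e-6) || (sdr < 1e-6);
    low[j] = lowc;
    if (sdl < 1e-6) sdl = 1e-6;
    if (sdr < 1e-6) sdr = 1e-6;
    for (arma::uword i = 0; i < ppx; ++i) {
      col[i] /= sdl;
      col[ppx + i] /= sdr;
    }
  }
  return List::create(_["x"] = X, _["low_contrast"] = low);
}

// Online subspace rotation: for each subspace n,
//   DeltaPhi_n = sum_j h_{n,j} * xtilde_{j,n} * (x_j' Phi_n)
//                / (||xhat_{j,n}|| ||x_j||),
// then Phi_n <- gram_schmidt(Phi_n + lambda * DeltaPhi_n).
// phi: dim x (2 n) flat basis matrix (modified copy returned).
// [[Rcpp::export]]
arma::mat gassom_update_core(const arma::mat& phi, const arma::mat& X,
                             const arma::mat& H, double lambda,
                             const LogicalVector& exclude) {
  const arma::uword dim = phi.n_rows;
  const arma::uword n = phi.n_cols / 2;
  const arma::uword P = X.n_cols;
  arma::mat out = phi;
  arma::vec xnorm(P);
  std::vector<bool> use(P);
  for (arma::uword j = 0; j < P; ++j) {
    xnorm[j] = arma::norm(X.col(j));
    use[j] = (xnorm[j] > 1e-12) && !exclude[j];
  }
  arma::vec d1(dim), d2(dim);
  for (arma::uword nn = 0; nn < n; ++nn) {
    const double* p1 = out.colptr(2 * nn);
    const double* p2 = out.colptr(2 * nn + 1);
    d1.zeros(); d2.zeros();
    bool any = false;
    for (arma::uword j = 0; j < P; ++j) {
      const double h = H(nn, j);
      if (!use[j] || h <= 1e-12) continue;
      const double* x = X.colptr(j);
      double c1 = 0.0, c2 = 0.0;
      for (arma::uword i = 0; i < dim; ++i) {
        c1 += p1[i] * x[i];
        c2 += p2[i] * x[i];
      }
      const double hatn = std::sqrt(c1 * c1 + c2 * c2);
      if (hatn <= 1e-12) continue;
      any = true;
      const double s = h / (hatn * xnorm[j]);
      // xtilde = x - (c1 p1 + c2 p2); DeltaPhi cols += s * xtilde * (c1, c2)
      for (arma::uword i = 0; i < dim; ++i) {
        const double xt = x[i] - c1 * p1[i] - c2 * p2[i];
        d1[i] += s * xt * c1;
        d2[i] += s * xt * c2;
      }
    }
    if (!any) continue;
    arma::vec q1 = out.col(2 * nn) + lambda * d1;
    arma::vec q2 = out.col(2 * nn + 1) + lambda * d2;
    q1 /= arma::norm(q1);
    q2 -= arma::dot(q1, q2) * q1;
    q2 /= arma::norm(q2);
    out.col(2 * nn) = q1;
    out.col(2 * nn + 1) = q2;
  }
  return out;
}
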