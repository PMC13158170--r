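// Evaluation of the synthetic anisotropic-Gaussian dose-rate kernels.
// Each (isocenter i, sector s, collimator c) triple has dose rate
//   phi(p) = amp[c] * exp(-(|q|^2 - kappa (d_s . q)^2) / (2 sigma[c]^2)),
// q = p - x_i, i.e. a Gaussian elongated along the sector axis d_s
// (inverse covariance (I - kappa d d')/sigma^2, kappa in [0,1)).
// Column order of the influence matrix: isocenter-major, then sector,
// then collimator innermost.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat influence_cpp(const arma::mat& P, const arma::mat& centers,
                        const arma::mat& dirs, const arma::vec& sigma,
                        const arma::vec& amp, double kappa) {
  const uword N = P.n_rows, ni = centers.n_rows, ns = dirs.n_rows,
              nc = sigma.n_elem;
  mat Phi(N, ni * ns * nc);
  vec inv2s2(nc);
  for (uword c = 0; c < nc; ++c) inv2s2(c) = 1.0 / (2.0 * sigma(c) * sigma(c));

  for (uword i = 0; i < ni; ++i) {
    mat Q = P.each_row() - centers.row(i);
    vec q2 = sum(square(Q), 1);
    for (uword s = 0; s < ns; ++s) {
      vec proj = Q * dirs.row(s).t();
      vec base = q2 - kappa * square(proj);
      for (uword c = 0; c < nc; ++c) {
        Phi.col((i * ns + s) * nc + c) = amp(c) * exp(-base * inv2s2(c));
      }
    }
  }
  return Phi;
}

// Dose accumulation for K plans sharing the kernel bank: returns an
// N x K matrix of doses at points P given sector times T (rows ordered
// as the influence columns).  Kernels whose time is zero in every plan
// are skipped, which preserves exact linearity.
// [[Rcpp::export]]
arma::mat dose_accumulate_cpp(const arma::mat& P, const arma::mat& centers,
                              const arma::mat& dirs, const arma::vec& sigma,
                              const arma::vec& amp, double kappa,
                              const arma::mat& T) {
  const uword N = P.n_rows, ni = centers.n_rows, ns = dirs.n_rows,
              nc = sigma.n_elem, K = T.n_cols;
  mat D(N, K, fill::zeros);
  vec inv2s2(nc);
  for (uword c = 0; c < nc; ++c) inv2s2(c) = 1.0 / (2.0 * sigma(c) * sigma(c));

  for (uword i = 0; i < ni; ++i) {
    // skip isocenters that are inactive in every plan
    const uword r0 = i * ns * nc;
    bool active = false;
    for (uword r = r0; r < r0 + ns * nc && !active; ++r)
      if (any(T.row(r) != 0.0)) active = true;
    if (!active) continue;

    mat Q = P.each_row() - centers.row(i);
    vec q2 = sum(square(Q), 1);
    for (uword s = 0; s < ns; ++s) {
      vec proj;
      bool have_proj = false;
      for (uword c = 0; c < nc; ++c) {
        const uword r = (i * ns + s) * nc + c;
        if (!any(T.row(r) != 0.0)) continue;
        if (!have_proj) {
          proj = Q * dirs.row(s).t();
          have_proj = true;
        }
        vec phi = amp(c) * exp(-(q2 - kappa * square(proj)) * inv2s2(c));
        D += phi * T.row(r);
      }
    }
  }
  return D;
}
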