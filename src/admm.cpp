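// Batched ADMM iterations for min c'x s.t. Ax <= b, l <= x <= u.
// All K weight-vector instances share A (and the cached Schur inverse);
// per-instance data are the columns of B, U and the entries of rho.
// The iteration arithmetic is templated so that it can run in genuine
// IEEE single precision (arma::fmat) or in double precision; the Schur
// inverse is always computed in double upstream and cast here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

template <typename eT>
static Rcpp::List admm_run(const Mat<eT>& A, const Mat<eT>& Sinv,
                           const Col<eT>& cvec, const Col<eT>& rho,
                           const Mat<eT>& B, const Mat<eT>& U,
                           const Mat<eT>& L,
                           Mat<eT> Z1, Mat<eT> Z2, Mat<eT> Y1, Mat<eT> Y2,
                           const int n_iter, const int trace_stride) {
  const uword m = A.n_rows, n = A.n_cols, K = B.n_cols;

  // c / rho, fixed across iterations (one column per instance)
  Mat<eT> Crho(n, K);
  for (uword j = 0; j < K; ++j) Crho.col(j) = cvec / rho(j);

  const int n_rec = (trace_stride > 0) ? n_iter / trace_stride : 0;
  mat pres(std::max(n_rec, 0), K, fill::zeros);
  mat dres(std::max(n_rec, 0), K, fill::zeros);
  ivec rec_iter(std::max(n_rec, 0), fill::zeros);

  Mat<eT> M1(n, K), V(m, K), X1(n, K), X2(m, K), Z1n(n, K), Z2n(m, K);
  bool diverged = false;
  int k_done = 0;
  int rec = 0;

  for (int k = 0; k < n_iter; ++k) {
    const bool record = (trace_stride > 0) && ((k + 1) % trace_stride == 0);

    M1 = Z1 - Y1 - Crho;
    V = Sinv * (A * M1 - Z2 + Y2);
    X1 = M1 - A.t() * V;
    X2 = V + Z2 - Y2;

    Z1n = arma::min(arma::max(X1 + Y1, L), U);
    Z2n = arma::min(X2 + Y2, B);

    Y1 += X1 - Z1n;
    Y2 += X2 - Z2n;

    if (record && rec < n_rec) {
      for (uword j = 0; j < K; ++j) {
        const double pr = std::sqrt(accu(square(X1.col(j) - Z1n.col(j))) +
                                    accu(square(X2.col(j) - Z2n.col(j))));
        const double zn = std::sqrt(accu(square(Z1n.col(j))) +
                                    accu(square(Z2n.col(j))));
        const double dz = std::sqrt(accu(square(Z1n.col(j) - Z1.col(j))) +
                                    accu(square(Z2n.col(j) - Z2.col(j))));
        const double yn = std::sqrt(accu(square(Y1.col(j))) +
                                    accu(square(Y2.col(j))));
        const double r = static_cast<double>(rho(j));
        pres(rec, j) = pr / std::max(1.0, zn);
        dres(rec, j) = r * dz / std::max(1.0, r * yn);
      }
      rec_iter(rec) = k + 1;
      ++rec;
    }

    Z1 = Z1n;
    Z2 = Z2n;
    k_done = k + 1;

    if (!Z1.is_finite() || !Y2.is_finite()) {
      diverged = true;
      break;
    }
  }

  if (rec < n_rec) {
    pres.resize(rec, K);
    dres.resize(rec, K);
    rec_iter.resize(rec);
  }

  return Rcpp::List::create(
      Rcpp::Named("Z1") = conv_to<mat>::from(Z1),
      Rcpp::Named("Z2") = conv_to<mat>::from(Z2),
      Rcpp::Named("Y1") = conv_to<mat>::from(Y1),
      Rcpp::Named("Y2") = conv_to<mat>::from(Y2),
      Rcpp::Named("primal_res") = pres,
      Rcpp::Named("dual_res") = dres,
      Rcpp::Named("trace_iter") = rec_iter,
      Rcpp::Named("iterations") = k_done,
      Rcpp::Named("diverged") = diverged);
}

// [[Rcpp::export]]
Rcpp::List admm_iterate_cpp(const arma::mat& A, const arma::mat& Sinv,
                            const arma::vec& cvec, const arma::vec& rho,
                            const arma::mat& B, const arma::mat& U,
                            const arma::mat& L,
                            const arma::mat& Z1, const arma::mat& Z2,
                            const arma::mat& Y1, const arma::mat& Y2,
                            int n_iter, bool single_precision,
                            int trace_stride) {
  if (single_precision) {
    return admm_run<float>(conv_to<fmat>::from(A), conv_to<fmat>::from(Sinv),
                           conv_to<fvec>::from(cvec), conv_to<fvec>::from(rho),
                           conv_to<fmat>::from(B), conv_to<fmat>::from(U),
                           conv_to<fmat>::from(L), conv_to<fmat>::from(Z1),
                           conv_to<fmat>::from(Z2), conv_to<fmat>::from(Y1),
                           conv_to<fmat>::from(Y2), n_iter, trace_stride);
  }
  return admm_run<double>(A, Sinv, cvec, rho, B, U, L, Z1, Z2, Y1, Y2,
                          n_iter, trace_stride);
}
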