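// Batched multi-head self-attention over fixed-length records.
//
// Layout contract (shared with the R layers): activations are (B*L) x d
// matrices, record-major (row (b-1)*L + i holds position i of record b).
// Attention weights are returned as (B*L) x (nheads*L): row (b,i), column
// (h-1)*L + j holds A[b,h,i,j].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, int L, int nheads) {
  const int total = Q.n_rows, d = Q.n_cols;
  const int B = total / L, dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat O(total, d), A(total, nheads * L);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < nheads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat S = (Qb * Kb.t()) * scale;
      arma::vec m = arma::max(S, 1);
      S.each_col() -= m;
      arma::mat Ab = arma::exp(S);
      arma::vec rs = arma::sum(Ab, 1);
      Ab.each_col() /= rs;
      O.submat(r0, c0, r1, c1) = Ab * Vb;
      A.submat(r0, h * L, r1, h * L + L - 1) = Ab;
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& dO, const arma::mat& Q,
                       const arma::mat& K, const arma::mat& V,
                       const arma::mat& A, int L, int nheads) {
  const int total = Q.n_rows, d = Q.n_cols;
  const int B = total / L, dh = d / nheads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(total, d, arma::fill::zeros);
  arma::mat dK(total, d, arma::fill::zeros);
  arma::mat dV(total, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L, r1 = r0 + L - 1;
    for (int h = 0; h < nheads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat Ab = A.submat(r0, h * L, r1, h * L + L - 1);
      arma::mat dOb = dO.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Ab.t() * dOb;
      arma::mat dAb = dOb * Vb.t();
      arma::vec rs = arma::sum(dAb % Ab, 1);
      arma::mat dS = Ab % (dAb.each_col() - rs);
      dS *= scale;
      dQ.submat(r0, c0, r1, c1) = dS * Kb;
      dK.submat(r0, c0, r1, c1) = dS.t() * Qb;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
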