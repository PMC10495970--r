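// Batched multi-head scaled-dot-product attention kernels.
//
// Layout contract (shared with the R layers): row-major-by-sequence
// matrices, i.e. row (b-1)*T + t is position t of sequence b.  Attention
// weights are exchanged with R as a (B*Tq) x (H*Tk) matrix whose column
// block h holds the weights of head h (column (h-1)*Tk + j = key position
// j of the row's own sequence).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List attn_fwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  int B, int Tq, int Tk, int H, bool causal,
                  Nullable<NumericMatrix> key_mask) {
  const int d = Q.n_cols;
  const int dk = d / H;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat ctx(B * Tq, d, arma::fill::zeros);
  arma::mat A(B * Tq, H * Tk, arma::fill::zeros);
  arma::mat km;
  bool has_km = key_mask.isNotNull();
  if (has_km) km = as<arma::mat>(key_mask.get());

  for (int b = 0; b < B; ++b) {
    const int q0 = b * Tq, k0 = b * Tk;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk;
      arma::mat Qb = Q.submat(q0, c0, q0 + Tq - 1, c0 + dk - 1);
      arma::mat Kb = K.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1);
      arma::mat S = Qb * Kb.t() * scale;
      if (causal) {
        for (int i = 0; i < Tq; ++i)
          for (int j = i + 1; j < Tk; ++j) S(i, j) = -arma::datum::inf;
      }
      if (has_km) {
        for (int j = 0; j < Tk; ++j)
          if (km(b, j) <= 0) S.col(j).fill(-arma::datum::inf);
      }
      for (int i = 0; i < Tq; ++i) {
        double mx = S.row(i).max();
        arma::rowvec e = arma::exp(S.row(i) - mx);
        S.row(i) = e / arma::accu(e);
      }
      ctx.submat(q0, c0, q0 + Tq - 1, c0 + dk - 1) =
        S * V.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1);
      A.submat(q0, h * Tk, q0 + Tq - 1, h * Tk + Tk - 1) = S;
    }
  }
  return List::create(_["ctx"] = ctx, _["A"] = A);
}

// [[Rcpp::export]]
List attn_bwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const arma::mat& A, const arma::mat& dctx,
                  int B, int Tq, int Tk, int H) {
  const int d = Q.n_cols;
  const int dk = d / H;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat dQ(B * Tq, d, arma::fill::zeros);
  arma::mat dK(B * Tk, d, arma::fill::zeros);
  arma::mat dV(B * Tk, d, arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    const int q0 = b * Tq, k0 = b * Tk;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk;
      arma::mat Ab = A.submat(q0, h * Tk, q0 + Tq - 1, h * Tk + Tk - 1);
      arma::mat dctxb = dctx.submat(q0, c0, q0 + Tq - 1, c0 + dk - 1);
      arma::mat Vb = V.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1);
      arma::mat dA = dctxb * Vb.t();
      dV.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1) = Ab.t() * dctxb;
      arma::vec rs = arma::sum(dA % Ab, 1);
      arma::mat dS = Ab % (dA.each_col() - rs);
      dQ.submat(q0, c0, q0 + Tq - 1, c0 + dk - 1) =
        dS * K.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1) * scale;
      dK.submat(k0, c0, k0 + Tk - 1, c0 + dk - 1) =
        dS.t() * Q.submat(q0, c0, q0 + Tq - 1, c0 + dk - 1) * scale;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
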