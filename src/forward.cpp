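// Forward-only scoring path used by predict on large window batches.
// Mirrors the R implementation in nn.R exactly (im2col conv, ReLU, width-2
// max pool with identity below length 2, dense ReLU head, logistic output);
// the R path remains the training/backprop reference and the two are pinned
// together by tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void conv_relu_pool(const arma::cube& X, const arma::cube& W,
                                const arma::vec& b, int pool,
                                arma::cube& out) {
  const int N = X.n_rows, L = X.n_cols, Cin = X.n_slices;
  const int k = W.n_rows, Fout = W.n_slices;
  const int L_out = L - k + 1;
  arma::mat M(N * L_out, k * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int j = 0; j < k; ++j) {
      const int col = j + k * c;
      for (int l = 0; l < L_out; ++l) {
        M.col(col).subvec(l * N, (l + 1) * N - 1) = X.slice(c).col(l + j);
      }
    }
  }
  arma::mat Wm(const_cast<double*>(W.memptr()), k * Cin, Fout, false, true);
  arma::mat Z = M * Wm;
  Z.each_row() += b.t();
  Z.clamp(0.0, arma::datum::inf);
  // reshape to (N, L_out, Fout) then pool pairs of positions
  arma::cube Zc(Z.memptr(), N, L_out, Fout);
  if (pool > 1 && L_out >= 2) {
    const int L_p = L_out / 2;
    out.set_size(N, L_p, Fout);
    for (int f = 0; f < Fout; ++f) {
      for (int l = 0; l < L_p; ++l) {
        out.slice(f).col(l) = arma::max(Zc.slice(f).col(2 * l),
                                        Zc.slice(f).col(2 * l + 1));
      }
    }
  } else {
    out = Zc;
  }
}

// [[Rcpp::export(name = ".nn_forward_scores")]]
NumericVector nn_forward_scores(List inputs, List conv_weights,
                                List conv_biases, arma::mat dense_W,
                                arma::vec dense_b, arma::vec out_W,
                                double out_b, CharacterVector branches,
                                int pool) {
  std::vector<arma::mat> flats;
  int N = 0;
  for (int bi = 0; bi < branches.size(); ++bi) {
    std::string br = as<std::string>(branches[bi]);
    arma::cube X = as<arma::cube>(inputs[br]);
    N = X.n_rows;
    List Ws = conv_weights[br];
    List bs = conv_biases[br];
    arma::cube cur = X;
    for (int l = 0; l < Ws.size(); ++l) {
      arma::cube W = as<arma::cube>(Ws[l]);
      arma::vec b = as<arma::vec>(bs[l]);
      arma::cube nxt;
      conv_relu_pool(cur, W, b, pool, nxt);
      cur = nxt;
    }
    // flatten (N, L, F) -> (N, L*F); cube memory layout already matches
    flats.push_back(arma::mat(cur.memptr(), N, cur.n_cols * cur.n_slices));
  }
  arma::mat H = flats[0];
  for (size_t i = 1; i < flats.size(); ++i) H = arma::join_rows(H, flats[i]);
  arma::mat D = H * dense_W;
  D.each_row() += dense_b.t();
  D.clamp(0.0, arma::datum::inf);
  arma::vec logit = D * out_W + out_b;
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = 1.0 / (1.0 + std::exp(-logit[i]));
  return out;
}
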