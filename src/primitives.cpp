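// Hot numerical kernels: im2col 3x3 convolution (forward/backward) and
// connected-component labeling. Feature maps are (H*W) x C matrices in
// column-major pixel order (R's native matrix layout for an H x W image).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gather the 3x3 neighbourhood patches of x into an (HW) x (9*Cin) matrix.
// idx is an HW x 9 1-based index matrix into pixel rows; index HW+1 denotes
// zero padding. Column order of the result: offset varies fastest within
// each input channel, matching the weight layout used by the R layers.
static arma::mat im2col3(const arma::mat& x, const arma::imat& idx) {
  const arma::uword HW = x.n_rows, Cin = x.n_cols;
  arma::mat P(HW, 9 * Cin);
  for (arma::uword c = 0; c < Cin; ++c) {
    const double* xc = x.colptr(c);
    for (arma::uword k = 0; k < 9; ++k) {
      double* pc = P.colptr(c * 9 + k);
      const arma::sword* ic = idx.colptr(k);
      for (arma::uword i = 0; i < HW; ++i) {
        arma::sword j = ic[i];
        pc[i] = (j > (arma::sword)HW) ? 0.0 : xc[j - 1];
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::mat conv3_forward(const arma::mat& x, const arma::imat& idx,
                        const arma::mat& w, const arma::rowvec& b) {
  arma::mat out = im2col3(x, idx) * w;
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
List conv3_backward(const arma::mat& x, const arma::imat& idx,
                    const arma::mat& w, const arma::mat& dout) {
  const arma::uword HW = x.n_rows, Cin = x.n_cols;
  arma::mat P = im2col3(x, idx);
  arma::mat dw = P.t() * dout;
  arma::rowvec db = arma::sum(dout, 0);
  arma::mat dP = dout * w.t();            // HW x (9*Cin)
  arma::mat dx(HW, Cin, arma::fill::zeros);
  // scatter-add: for a fixed offset k the map pixel -> neighbour is injective
  for (arma::uword c = 0; c < Cin; ++c) {
    double* xc = dx.colptr(c);
    for (arma::uword k = 0; k < 9; ++k) {
      const double* pc = dP.colptr(c * 9 + k);
      const arma::sword* ic = idx.colptr(k);
      for (arma::uword i = 0; i < HW; ++i) {
        arma::sword j = ic[i];
        if (j <= (arma::sword)HW) xc[j - 1] += pc[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// BFS flood-fill labeling of a binary H x W matrix. connectivity is 4 or 8.
// Returns an integer matrix of labels (0 = background, components 1..n).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(256);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * H + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int k = 0; k < nn; ++k) {
          int rr = pr + dr8[k], cc = pc + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(cc * H + rr);
          }
        }
      }
    }
  }
  return lab;
}
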