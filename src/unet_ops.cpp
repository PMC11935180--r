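// GEMM-based convolutional primitives for the U-Net enhancer.
// Feature maps are H x W x C cubes (R arrays dim c(H, W, C)); 3x3 'same'
// convolutions use im2col + matrix multiply. Weight matrix layout:
// (Cout) x (Cin * k * k), row-index order inside a row: ci * k * k + dr * k + dc.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat cols(C * k * k, H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& sl = x.slice(ci);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        int rowidx = ci * k * k + dr * k + dc;
        for (int w = 0; w < W; ++w) {
          int sc = w + dc - pad;
          if (sc < 0 || sc >= W) continue;
          for (int h = 0; h < H; ++h) {
            int sr = h + dr - pad;
            if (sr < 0 || sr >= H) continue;
            cols(rowidx, h + w * H) = sl(sr, sc);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& sl = x.slice(ci);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        int rowidx = ci * k * k + dr * k + dc;
        for (int w = 0; w < W; ++w) {
          int sc = w + dc - pad;
          if (sc < 0 || sc >= W) continue;
          for (int h = 0; h < H; ++h) {
            int sr = h + dr - pad;
            if (sr < 0 || sr >= H) continue;
            sl(sr, sc) += cols(rowidx, h + w * H);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& Wmat,
                      const arma::vec& bias, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wmat.n_rows;
  arma::mat cols = im2col(x, k);
  arma::mat O = Wmat * cols;             // Cout x (H*W)
  O.each_col() += bias;
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(O.row(co).t(), H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& Wmat,
                    const arma::cube& dY, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dY.n_slices;
  arma::mat dY_mat(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    dY_mat.row(co) = arma::vectorise(dY.slice(co)).t();
  arma::mat cols = im2col(x, k);
  arma::mat dW = dY_mat * cols.t();
  arma::vec db = arma::sum(dY_mat, 1);
  arma::mat dcols = Wmat.t() * dY_mat;
  arma::cube dx = col2im(dcols, H, W, Cin, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // 0..3: which corner (dr + 2*dc) won
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = -arma::datum::inf;
        unsigned bi = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            double v = x(2 * h + dr, 2 * w + dc, c);
            if (v > best) { best = v; bi = dr + 2 * dc; }
          }
        out(h, w, c) = best;
        idx(h, w, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dY, const arma::ucube& idx) {
  const int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        unsigned bi = idx(h, w, c);
        dx(2 * h + (bi % 2), 2 * w + (bi / 2), c) = dY(h, w, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;
        out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v;
        out(2 * h + 1, 2 * w + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dY) {
  const int Ho = dY.n_rows / 2, Wo = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        dx(h, w, c) = dY(2 * h, 2 * w, c) + dY(2 * h + 1, 2 * w, c) +
                      dY(2 * h, 2 * w + 1, c) + dY(2 * h + 1, 2 * w + 1, c);
  return dx;
}
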