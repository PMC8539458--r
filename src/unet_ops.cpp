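// Convolutional building blocks for the package's compact U-Net.
// All cubes are (rows = H, cols = W, slices = channels); convolution
// weights are (9 * C_in) x C_out matrices with row order
// channel * 9 + (dx + 1) * 3 + (dy + 1), matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 3x3 im2col with zero padding 1: (9*C) x (H*W), pixel linear index r + c*H
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(9 * C, H * W, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    const mat& sl = x.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword row = ch * 9 + (dc + 1) * 3 + (dr + 1);
        double* orow = out.memptr();
        for (uword c = 0; c < W; ++c) {
          const int sc = (int)c + dc;
          if (sc < 0 || sc >= (int)W) continue;
          for (uword r = 0; r < H; ++r) {
            const int sr = (int)r + dr;
            if (sr < 0 || sr >= (int)H) continue;
            // column index r + c*H, row `row`; col-major storage
            orow[row + (r + c * H) * 9 * C] = sl((uword)sr, (uword)sc);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add counterpart of im2col3
static cube col2im3(const mat& cols, uword H, uword W, uword C) {
  cube x(H, W, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    mat& sl = x.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const uword row = ch * 9 + (dc + 1) * 3 + (dr + 1);
        const double* cp = cols.memptr();
        for (uword c = 0; c < W; ++c) {
          const int sc = (int)c + dc;
          if (sc < 0 || sc >= (int)W) continue;
          for (uword r = 0; r < H; ++r) {
            const int sr = (int)r + dr;
            if (sr < 0 || sr >= (int)H) continue;
            sl((uword)sr, (uword)sc) += cp[row + (r + c * H) * 9 * C];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv3x3_fw(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  if (w.n_rows != 9 * x.n_slices)
    Rcpp::stop("conv weight shape does not match input channels");
  mat cols = im2col3(x);
  mat y = w.t() * cols;            // Cout x (H*W)
  y.each_col() += b;
  cube out(H, W, Cout);
  for (uword k = 0; k < Cout; ++k)
    out.slice(k) = reshape(y.row(k).t(), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3x3_bw(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Cout = w.n_cols;
  mat gym(Cout, H * W);
  for (uword k = 0; k < Cout; ++k)
    gym.row(k) = vectorise(gy.slice(k)).t();
  mat cols = im2col3(x);
  mat gw = cols * gym.t();         // (9C) x Cout
  vec gb = sum(gym, 1);
  mat gcols = w * gym;             // (9C) x (H*W)
  cube gx = col2im3(gcols, H, W, C);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2; H and W must be even
// [[Rcpp::export]]
arma::cube cpp_maxpool2_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) Rcpp::stop("maxpool input must have even sides");
  cube y(H / 2, W / 2, C);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < W / 2; ++c)
      for (uword r = 0; r < H / 2; ++r) {
        const mat& sl = x.slice(ch);
        double m = sl(2 * r, 2 * c);
        m = std::max(m, sl(2 * r + 1, 2 * c));
        m = std::max(m, sl(2 * r, 2 * c + 1));
        m = std::max(m, sl(2 * r + 1, 2 * c + 1));
        y(r, c, ch) = m;
      }
  return y;
}

// backward of 2x2 max pooling; gradient flows to the first maximal element
// (row-major scan order within the window), deterministically
// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& x, const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < W / 2; ++c)
      for (uword r = 0; r < H / 2; ++r) {
        const mat& sl = x.slice(ch);
        uword br = 2 * r, bc = 2 * c;
        double m = sl(br, bc);
        if (sl(2 * r + 1, 2 * c) > m) { m = sl(2 * r + 1, 2 * c); br = 2 * r + 1; bc = 2 * c; }
        if (sl(2 * r, 2 * c + 1) > m) { m = sl(2 * r, 2 * c + 1); br = 2 * r; bc = 2 * c + 1; }
        if (sl(2 * r + 1, 2 * c + 1) > m) { br = 2 * r + 1; bc = 2 * c + 1; }
        gx(br, bc, ch) += gy(r, c, ch);
      }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < W; ++c)
      for (uword r = 0; r < H; ++r) {
        const double v = x(r, c, ch);
        y(2 * r, 2 * c, ch) = v;
        y(2 * r + 1, 2 * c, ch) = v;
        y(2 * r, 2 * c + 1, ch) = v;
        y(2 * r + 1, 2 * c + 1, ch) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < W; ++c)
      for (uword r = 0; r < H; ++r)
        gx(r, c, ch) = gy(2 * r, 2 * c, ch) + gy(2 * r + 1, 2 * c, ch) +
                       gy(2 * r, 2 * c + 1, ch) + gy(2 * r + 1, 2 * c + 1, ch);
  return gx;
}
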