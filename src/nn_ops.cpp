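// Minimal CNN kernels: stride-1 'same' convolutions (2D and batched 1D),
// 2x2/stride-2 transpose convolution and max pooling, forward and backward.
// Layout conventions (column-major, matching R arrays):
//   2D feature map: cube (H, W, C), one sample per call.
//   1D feature map: cube (L, C, B), whole mini-batch per call.
//   conv2d weights: mat (Cout, Cin*KH*KW), column index (ci*KH + dr)*KW + dc.
//   conv1d weights: mat (Cout, Cin*K),     column index ci*K + dk.
//   convT2d weights: mat (Cout*4, Cin),    row index co*4 + dr*2 + dc.
// All functions are pure; randomness and parameter updates live in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static mat im2col2d(const cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat cols(C * kh * kw, H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dr = 0; dr < kh; ++dr)
      for (int dc = 0; dc < kw; ++dc) {
        const int r = (c * kh + dr) * kw + dc;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc - pw;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, ph - dr);
          const int i1 = std::min(H, H + ph - dr);
          for (int i = i0; i < i1; ++i)
            cols(r, i + j * H) = x(i + dr - ph, sj, c);
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat y = w * im2col2d(x, kh, kw);  // (Cout, H*W)
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.row(co).t(), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& x, const arma::mat& w,
               const arma::cube& gy, const int kh, const int kw,
               const bool need_gx = true) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat gym(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    gym.row(co) = vectorise(gy.slice(co)).t();
  mat cols = im2col2d(x, kh, kw);
  mat gw = gym * cols.t();
  vec gb = sum(gym, 1);
  cube gx(H, W, Cin, fill::zeros);
  if (need_gx) {
  mat gcols = w.t() * gym;  // (Cin*kh*kw, H*W)
  for (int c = 0; c < Cin; ++c)
    for (int dr = 0; dr < kh; ++dr)
      for (int dc = 0; dc < kw; ++dc) {
        const int r = (c * kh + dr) * kw + dc;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc - pw;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, ph - dr);
          const int i1 = std::min(H, H + ph - dr);
          for (int i = i0; i < i1; ++i)
            gx(i + dr - ph, sj, c) += gcols(r, i + j * H);
        }
      }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// forward that also returns the im2col matrix so the backward pass can
// reuse it instead of rebuilding it
// [[Rcpp::export]]
List conv2d_fwc(const arma::cube& x, const arma::mat& w,
                const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat cols = im2col2d(x, kh, kw);
  mat y = w * cols;
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.row(co).t(), H, W);
  return List::create(Rcpp::Named("y") = out, Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
List conv2d_bwc(const arma::mat& cols, const arma::mat& w,
                const arma::cube& gy, const int kh, const int kw,
                const int Cin, const bool need_gx = true) {
  const int H = gy.n_rows, W = gy.n_cols;
  const int Cout = gy.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat gym(Cout, H * W);
  for (int co = 0; co < Cout; ++co)
    gym.row(co) = vectorise(gy.slice(co)).t();
  mat gw = gym * cols.t();
  vec gb = sum(gym, 1);
  cube gx(H, W, Cin, fill::zeros);
  if (need_gx) {
    mat gcols = w.t() * gym;
    for (int c = 0; c < Cin; ++c)
      for (int dr = 0; dr < kh; ++dr)
        for (int dc = 0; dc < kw; ++dc) {
          const int r = (c * kh + dr) * kw + dc;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dc - pw;
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, ph - dr);
            const int i1 = std::min(H, H + ph - dr);
            for (int i = i0; i < i1; ++i)
              gx(i + dr - ph, sj, c) += gcols(r, i + j * H);
          }
        }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2; H and W must be even. idx stores 0-based linear
// indices into x so the backward pass routes gradients to the argmax.
// [[Rcpp::export]]
List maxpool2d_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C);
  cube idx(H2, W2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        double best = -datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = si + sj * H + c * H * W; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2d_bw(const arma::cube& gy, const arma::cube& idx,
                        const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const double* gv = gy.memptr();
  const double* iv = idx.memptr();
  double* out = gx.memptr();
  const uword n = gy.n_elem;
  for (uword k = 0; k < n; ++k) out[(uword)iv[k]] += gv[k];
  return gx;
}

// Transpose convolution, kernel 2x2, stride 2 (doubles H and W).
// [[Rcpp::export]]
arma::cube convT2d_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows / 4;
  mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c) xm.row(c) = vectorise(x.slice(c)).t();
  mat m = w * xm;  // (Cout*4, H*W)
  cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co).fill(b(co));
    for (int dr = 0; dr < 2; ++dr)
      for (int dc = 0; dc < 2; ++dc) {
        const int r = co * 4 + dr * 2 + dc;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + dr, 2 * j + dc, co) += m(r, i + j * H);
      }
  }
  return y;
}

// [[Rcpp::export]]
List convT2d_bw(const arma::cube& x, const arma::mat& w,
                const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows / 4;
  mat xm(Cin, H * W);
  for (int c = 0; c < Cin; ++c) xm.row(c) = vectorise(x.slice(c)).t();
  mat gm(Cout * 4, H * W);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = accu(gy.slice(co));
    for (int dr = 0; dr < 2; ++dr)
      for (int dc = 0; dc < 2; ++dc) {
        const int r = co * 4 + dr * 2 + dc;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            gm(r, i + j * H) = gy(2 * i + dr, 2 * j + dc, co);
      }
  }
  mat gw = gm * xm.t();
  mat gxm = w.t() * gm;  // (Cin, H*W)
  cube gx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    gx.slice(c) = reshape(gxm.row(c).t(), H, W);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

static mat im2col1d(const cube& x, const int k) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int p = (k - 1) / 2;
  mat cols(C * k, (uword)L * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int dk = 0; dk < k; ++dk) {
        const int r = c * k + dk;
        const int t0 = std::max(0, p - dk);
        const int t1 = std::min(L, L + p - dk);
        for (int t = t0; t < t1; ++t)
          cols(r, t + (uword)b * L) = x(t + dk - p, c, b);
      }
  return cols;
}

// Batched 1D 'same' convolution: x (L, Cin, B) -> (L, Cout, B).
// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, const int k,
                     const bool act = false) {
  const int L = x.n_rows, B = x.n_slices;
  const int Cout = w.n_rows;
  mat y = w * im2col1d(x, k);  // (Cout, L*B)
  y.each_col() += b;
  if (act) y = tanh(y);
  cube out(L, Cout, B);
  for (int bb = 0; bb < B; ++bb)
    out.slice(bb) = y.cols((uword)bb * L, (uword)(bb + 1) * L - 1).t();
  return out;
}

// [[Rcpp::export]]
List conv1d_bw(const arma::cube& x, const arma::mat& w,
               const arma::cube& gy, const int k,
               const bool need_gx = true) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int Cout = gy.n_cols;
  const int p = (k - 1) / 2;
  mat gym(Cout, (uword)L * B);
  for (int bb = 0; bb < B; ++bb)
    gym.cols((uword)bb * L, (uword)(bb + 1) * L - 1) = gy.slice(bb).t();
  mat cols = im2col1d(x, k);
  mat gw = gym * cols.t();
  vec gb = sum(gym, 1);
  cube gx(L, Cin, B, fill::zeros);
  if (need_gx) {
  mat gcols = w.t() * gym;  // (Cin*k, L*B)
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < Cin; ++c)
      for (int dk = 0; dk < k; ++dk) {
        const int r = c * k + dk;
        const int t0 = std::max(0, p - dk);
        const int t1 = std::min(L, L + p - dk);
        for (int t = t0; t < t1; ++t)
          gx(t + dk - p, c, bb) += gcols(r, t + (uword)bb * L);
      }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
List conv1d_fwc(const arma::cube& x, const arma::mat& w,
                const arma::vec& b, const int k, const bool act = false) {
  const int L = x.n_rows, B = x.n_slices;
  const int Cout = w.n_rows;
  mat cols = im2col1d(x, k);
  mat y = w * cols;
  y.each_col() += b;
  if (act) y = tanh(y);
  cube out(L, Cout, B);
  for (int bb = 0; bb < B; ++bb)
    out.slice(bb) = y.cols((uword)bb * L, (uword)(bb + 1) * L - 1).t();
  return List::create(Rcpp::Named("y") = out, Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
List conv1d_bwc(const arma::mat& cols, const arma::mat& w,
                const arma::cube& gy, const int k, const int Cin,
                const bool need_gx = true) {
  const int L = gy.n_rows, B = gy.n_slices;
  const int Cout = gy.n_cols;
  const int p = (k - 1) / 2;
  mat gym(Cout, (uword)L * B);
  for (int bb = 0; bb < B; ++bb)
    gym.cols((uword)bb * L, (uword)(bb + 1) * L - 1) = gy.slice(bb).t();
  mat gw = gym * cols.t();
  vec gb = sum(gym, 1);
  cube gx(L, Cin, B, fill::zeros);
  if (need_gx) {
    mat gcols = w.t() * gym;
    for (int bb = 0; bb < B; ++bb)
      for (int c = 0; c < Cin; ++c)
        for (int dk = 0; dk < k; ++dk) {
          const int r = c * k + dk;
          const int t0 = std::max(0, p - dk);
          const int t1 = std::min(L, L + p - dk);
          for (int t = t0; t < t1; ++t)
            gx(t + dk - p, c, bb) += gcols(r, t + (uword)bb * L);
        }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// 1D max pooling, stride = pool size; L must be divisible by p.
// [[Rcpp::export]]
List maxpool1d_fw(const arma::cube& x, const int p) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  const int L2 = L / p;
  cube y(L2, C, B);
  cube idx(L2, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < L2; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int d = 0; d < p; ++d) {
          const int si = i * p + d;
          const double v = x(si, c, b);
          if (v > best) {
            best = v;
            bi = (uword)si + (uword)c * L + (uword)b * L * C;
          }
        }
        y(i, c, b) = best;
        idx(i, c, b) = (double)bi;
      }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool1d_bw(const arma::cube& gy, const arma::cube& idx,
                        const int L) {
  const int C = gy.n_cols, B = gy.n_slices;
  cube gx(L, C, B, fill::zeros);
  const double* gv = gy.memptr();
  const double* iv = idx.memptr();
  double* out = gx.memptr();
  const uword n = gy.n_elem;
  for (uword k = 0; k < n; ++k) out[(uword)iv[k]] += gv[k];
  return gx;
}
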