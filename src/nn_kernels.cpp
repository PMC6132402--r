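// Minimal dense-network kernels: batched im2col convolution (stride 1),
// 2x2 max-pooling with argmax indices, index unpooling, nearest upsampling,
// and trilinear volume sampling. Batches of N images with C channels are
// stored as an arma::cube of size (H, W, N*C), sample-major (slice n*C + c).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// Fill `out` ((Ho*Wo) x (k*k*C)) with the im2col matrix of sample n.
// Row index is i + j*Ho (column-major over output pixels); column index is
// c*k*k + dr*k + dc. `out` must be zeroed by the caller (zero padding).
static void im2col_one(const cube& x, const int n, const int C, const int k,
                       const int pad, mat& out) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(n * C + c);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int col = c * k * k + dr * k + dc;
        for (int j = 0; j < Wo; ++j) {
          const int sc = j + dc - pad;
          if (sc < 0 || sc >= W) continue;
          const int i0 = std::max(0, pad - dr);
          const int i1 = std::min(Ho, H + pad - dr);
          for (int i = i0; i < i1; ++i) {
            out(i + j * Ho, col) = xs(i + dr - pad, sc);
          }
        }
      }
    }
  }
}

// Scatter-add of a dXcol matrix back onto sample n of dx (col2im transpose).
static void col2im_add_one(cube& dx, const int n, const int C, const int k,
                           const int pad, const mat& dcol) {
  const int H = dx.n_rows, W = dx.n_cols;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(n * C + c);
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int col = c * k * k + dr * k + dc;
        for (int j = 0; j < Wo; ++j) {
          const int sc = j + dc - pad;
          if (sc < 0 || sc >= W) continue;
          const int i0 = std::max(0, pad - dr);
          const int i1 = std::min(Ho, H + pad - dr);
          for (int i = i0; i < i1; ++i) {
            xs(i + dr - pad, sc) += dcol(i + j * Ho, col);
          }
        }
      }
    }
  }
}

// Stacked im2col over the whole batch: rows are output pixels of sample 0,
// then sample 1, ... -- one GEMM serves the batch (small per-sample GEMMs
// are overhead-bound).
static mat im2col_batch(const cube& x, const int n_batch, const int C,
                        const int k, const int pad) {
  const int Ho = x.n_rows + 2 * pad - k + 1;
  const int Wo = x.n_cols + 2 * pad - k + 1;
  mat xcol(Ho * Wo * n_batch, k * k * C, fill::zeros);
  for (int n = 0; n < n_batch; ++n) {
    mat sub(Ho * Wo, k * k * C, fill::zeros);
    im2col_one(x, n, C, k, pad, sub);
    xcol.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1) = sub;
  }
  return xcol;
}

// x: (H, W, N*Cin); w: (k*k*Cin) x Cout; b: Cout. Returns (Ho, Wo, N*Cout).
// [[Rcpp::export]]
arma::cube nn_conv2d_forward(const arma::cube& x, const arma::mat& w,
                             const arma::vec& b, const int n_batch,
                             const int k, const int pad) {
  const int C = x.n_slices / n_batch;
  const int Cout = w.n_cols;
  const int Ho = x.n_rows + 2 * pad - k + 1;
  const int Wo = x.n_cols + 2 * pad - k + 1;
  if ((int)w.n_rows != k * k * C)
    stop("weight rows (%d) != k*k*Cin (%d)", (int)w.n_rows, k * k * C);
  mat xcol = im2col_batch(x, n_batch, C, k, pad);
  mat ym = xcol * w;              // (Ho*Wo*N) x Cout
  ym.each_row() += b.t();
  cube y(Ho, Wo, n_batch * Cout);
  for (int n = 0; n < n_batch; ++n)
    for (int co = 0; co < Cout; ++co)
      y.slice(n * Cout + co) =
          reshape(ym.col(co).subvec(n * Ho * Wo, (n + 1) * Ho * Wo - 1),
                  Ho, Wo);
  return y;
}

// Backward pass; dy: (Ho, Wo, N*Cout). Returns dx, dw, db.
// [[Rcpp::export]]
Rcpp::List nn_conv2d_backward(const arma::cube& x, const arma::mat& w,
                              const arma::cube& dy, const int n_batch,
                              const int k, const int pad) {
  const int C = x.n_slices / n_batch;
  const int Cout = w.n_cols;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  mat dym(Ho * Wo * n_batch, Cout);
  for (int n = 0; n < n_batch; ++n)
    for (int co = 0; co < Cout; ++co)
      dym.col(co).subvec(n * Ho * Wo, (n + 1) * Ho * Wo - 1) =
          vectorise(dy.slice(n * Cout + co));
  mat xcol = im2col_batch(x, n_batch, C, k, pad);
  mat dw = xcol.t() * dym;
  vec db = sum(dym, 0).t();
  mat dcol = dym * w.t();
  for (int n = 0; n < n_batch; ++n)
    col2im_add_one(dx, n, C, k, pad,
                   dcol.rows(n * Ho * Wo, (n + 1) * Ho * Wo - 1));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling on every slice; dims must be even. Returns pooled cube and
// an argmax index cube with values in {0,1,2,3} = dr*2 + dc.
// [[Rcpp::export]]
Rcpp::List nn_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  if (H % 2 || W % 2) stop("max-pool input dims must be even, got %dx%d", H, W);
  cube y(H / 2, W / 2, S);
  icube idx(H / 2, W / 2, S);
  for (int s = 0; s < S; ++s) {
    const mat& xs = x.slice(s);
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double best = xs(2 * i, 2 * j);
        int arg = 0;
        for (int dr = 0; dr < 2; ++dr)
          for (int dc = 0; dc < 2; ++dc) {
            const double v = xs(2 * i + dr, 2 * j + dc);
            if (v > best) { best = v; arg = dr * 2 + dc; }
          }
        y(i, j, s) = best;
        idx(i, j, s) = arg;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Place y's values at the recorded argmax positions, zeros elsewhere.
// Doubles as the max-pool backward pass.
// [[Rcpp::export]]
arma::cube nn_unpool2(const arma::cube& y, const arma::icube& idx) {
  const int Ho = y.n_rows, Wo = y.n_cols, S = y.n_slices;
  cube x(2 * Ho, 2 * Wo, S, fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, s);
        x(2 * i + a / 2, 2 * j + a % 2, s) = y(i, j, s);
      }
  return x;
}

// Gather from the full-resolution grid at the recorded argmax positions.
// Backward pass of nn_unpool2.
// [[Rcpp::export]]
arma::cube nn_pool_gather(const arma::cube& x, const arma::icube& idx) {
  const int Ho = idx.n_rows, Wo = idx.n_cols, S = idx.n_slices;
  cube y(Ho, Wo, S);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = idx(i, j, s);
        y(i, j, s) = x(2 * i + a / 2, 2 * j + a % 2, s);
      }
  return y;
}

// Nearest-neighbour upsampling by an integer factor on every slice.
// [[Rcpp::export]]
arma::cube nn_upsample_nearest(const arma::cube& x, const int f) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  cube y(H * f, W * f, S);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < W * f; ++j)
      for (int i = 0; i < H * f; ++i)
        y(i, j, s) = x(i / f, j / f, s);
  return y;
}

// Box-sum downsampling by factor f (backward of nearest upsampling).
// [[Rcpp::export]]
arma::cube nn_downsample_sum(const arma::cube& x, const int f) {
  const int H = x.n_rows / f, W = x.n_cols / f, S = x.n_slices;
  cube y(H, W, S, fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < (int)x.n_cols; ++j)
      for (int i = 0; i < (int)x.n_rows; ++i)
        y(i / f, j / f, s) += x(i, j, s);
  return y;
}

// Trilinear sampling of a 3D grid at continuous 0-based index coordinates.
// pts: N x 3 (rows are (i, j, k) positions). Out-of-range samples are `fill`.
// nearest = true switches to nearest-neighbour (for label volumes).
// [[Rcpp::export]]
arma::vec nn_trilinear_sample(const arma::cube& v, const arma::mat& pts,
                              const double fill, const bool nearest) {
  const int n = pts.n_rows;
  const int d1 = v.n_rows, d2 = v.n_cols, d3 = v.n_slices;
  vec out(n);
  for (int r = 0; r < n; ++r) {
    const double pi = pts(r, 0), pj = pts(r, 1), pk = pts(r, 2);
    if (nearest) {
      const int i = (int)std::lround(pi), j = (int)std::lround(pj),
                k = (int)std::lround(pk);
      out(r) = (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3)
                   ? fill : v(i, j, k);
      continue;
    }
    if (pi < 0 || pj < 0 || pk < 0 || pi > d1 - 1 || pj > d2 - 1 ||
        pk > d3 - 1) {
      out(r) = fill;
      continue;
    }
    const int i0 = std::min((int)std::floor(pi), d1 - 2 >= 0 ? d1 - 2 : 0);
    const int j0 = std::min((int)std::floor(pj), d2 - 2 >= 0 ? d2 - 2 : 0);
    const int k0 = std::min((int)std::floor(pk), d3 - 2 >= 0 ? d3 - 2 : 0);
    const double fi = pi - i0, fj = pj - j0, fk = pk - k0;
    const int i1 = std::min(i0 + 1, d1 - 1), j1 = std::min(j0 + 1, d2 - 1),
              k1 = std::min(k0 + 1, d3 - 1);
    const double c00 = v(i0, j0, k0) * (1 - fi) + v(i1, j0, k0) * fi;
    const double c10 = v(i0, j1, k0) * (1 - fi) + v(i1, j1, k0) * fi;
    const double c01 = v(i0, j0, k1) * (1 - fi) + v(i1, j0, k1) * fi;
    const double c11 = v(i0, j1, k1) * (1 - fi) + v(i1, j1, k1) * fi;
    out(r) = (c00 * (1 - fj) + c10 * fj) * (1 - fk) +
             (c01 * (1 - fj) + c11 * fj) * fk;
  }
  return out;
}
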