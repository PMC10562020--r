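// Low-level numeric kernels: 2-D convolution stack used by the attention-gated
// U-Net (forward and backward passes), image resampling/warping, and
// surface-distance helpers. Tensors are R arrays dim (H, W, C), column-major,
// mapped onto arma::cube without copying layout changes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------- im2col / col2im ----------
// P(H*W, k*k*C): row = i + H*j, col = a + k*b + k*k*c, zero padding `pad`.
static arma::mat im2col_pad(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat P(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * c;
        double* Pc = P.colptr(col);
        const double* Xc = x.slice_memptr(c);
        const int i0 = std::max(0, pad - a), i1 = std::min(H, H + pad - a);
        const int j0 = std::max(0, pad - b), j1 = std::min(W, W + pad - b);
        if (i0 >= i1) continue;
        for (int j = j0; j < j1; ++j) {
          const int sj = j + b - pad;
          std::memcpy(Pc + i0 + H * j, Xc + (i0 + a - pad) + H * sj,
                      sizeof(double) * (i1 - i0));
        }
      }
  return P;
}

static void col2im_acc(arma::cube& dx, const arma::mat& dP, int k, int pad) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * c;
        const double* Pc = dP.colptr(col);
        double* Xc = dx.slice_memptr(c);
        const int i0 = std::max(0, pad - a), i1 = std::min(H, H + pad - a);
        const int j0 = std::max(0, pad - b), j1 = std::min(W, W + pad - b);
        if (i0 >= i1) continue;
        for (int j = j0; j < j1; ++j) {
          const int sj = j + b - pad;
          double* xp = Xc + (i0 + a - pad) + H * sj;
          const double* pp = Pc + i0 + H * j;
          for (int i = 0; i < i1 - i0; ++i) xp[i] += pp[i];
        }
      }
}

// weight matrix w: (k*k*Cin) x Cout, rows ordered a + k*b + k*k*cin.
// [[Rcpp::export]]
arma::cube cc_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat P = im2col_pad(x, k, pad);
  arma::mat Y = P * w;
  Y.each_row() += b.t();
  return arma::cube(Y.memptr(), H, W, w.n_cols);
}

// [[Rcpp::export]]
List cc_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  arma::mat P = im2col_pad(x, k, pad);
  arma::mat dY(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  arma::mat dW = P.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dP = dY * w.t();
  arma::cube dx(H, W, x.n_slices, arma::fill::zeros);
  col2im_acc(dx, dP, k, pad);
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// ---------- 2x2 transposed convolution, stride 2 (no overlap) ----------
// weight matrix w: (4*Cin) x Cout, rows ordered a + 2*b + 4*cin.
// [[Rcpp::export]]
arma::cube cc_convt2_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, Cout = w.n_cols;
  arma::mat X(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  arma::cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int bb = 0; bb < 2; ++bb)
    for (int aa = 0; aa < 2; ++aa) {
      arma::mat Wab(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci)
        Wab.row(ci) = w.row(aa + 2 * bb + 4 * ci);
      arma::mat Yab = X * Wab;  // (H*W) x Cout
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + aa, 2 * j + bb, co) += Yab(i + H * j, co);
    }
  return y;
}

// [[Rcpp::export]]
List cc_convt2_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, Cout = w.n_cols;
  arma::mat X(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  arma::mat dW(4 * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dXacc(H * W, Cin, arma::fill::zeros);
  for (int bb = 0; bb < 2; ++bb)
    for (int aa = 0; aa < 2; ++aa) {
      arma::mat dYab(H * W, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            dYab(i + H * j, co) = dy(2 * i + aa, 2 * j + bb, co);
      arma::mat Wab(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci)
        Wab.row(ci) = w.row(aa + 2 * bb + 4 * ci);
      dXacc += dYab * Wab.t();
      arma::mat dWab = X.t() * dYab;  // Cin x Cout
      for (int ci = 0; ci < Cin; ++ci)
        dW.row(aa + 2 * bb + 4 * ci) += dWab.row(ci);
      db += arma::sum(dYab, 0).t();
    }
  std::memcpy(dx.memptr(), dXacc.memptr(), sizeof(double) * H * W * Cin);
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// ---------- 2x2 max pooling ----------
// [[Rcpp::export]]
List cc_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  IntegerVector arg(h * w * C);
  int idx = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int ab = 0;
        for (int q = 1; q < 4; ++q) {
          const int a = q % 2, b = q / 2;
          const double v = x(2 * i + a, 2 * j + b, c);
          if (v > best) { best = v; ab = q; }
        }
        y(i, j, c) = best;
        arg[idx++] = ab;
      }
  arg.attr("dim") = IntegerVector::create(h, w, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cc_maxpool2_bwd(const arma::cube& dy, const IntegerVector& arg) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  int idx = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const int q = arg[idx++];
        dx(2 * i + q % 2, 2 * j + q / 2, c) += dy(i, j, c);
      }
  return dx;
}

// ---------- nearest-neighbour x2 upsampling ----------
// [[Rcpp::export]]
arma::cube cc_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export]]
arma::cube cc_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        dx(i / 2, j / 2, c) += dy(i, j, c);
  return dx;
}

// ---------- sampling ----------
static inline double sample_at(const arma::mat& img, double r, double c,
                               bool nearest, bool clamp = false) {
  const int H = img.n_rows, W = img.n_cols;
  if (!clamp && (r < -0.5 || c < -0.5 || r > H - 0.5 || c > W - 0.5))
    return 0.0;
  if (r < 0) r = 0; if (c < 0) c = 0;
  if (r > H - 1) r = H - 1; if (c > W - 1) c = W - 1;
  if (nearest) {
    return img((int)std::floor(r + 0.5) < H ? (int)std::floor(r + 0.5) : H - 1,
               (int)std::floor(c + 0.5) < W ? (int)std::floor(c + 0.5) : W - 1);
  }
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
  const double fr = r - r0, fc = c - c0;
  return img(r0, c0) * (1 - fr) * (1 - fc) + img(r1, c0) * fr * (1 - fc) +
         img(r0, c1) * (1 - fr) * fc + img(r1, c1) * fr * fc;
}

// out(i,j) = img(i*sy + oy, j*sx + ox), 0-based voxel-centred coordinates.
// With clamp = false samples beyond the half-voxel border are zero; with
// clamp = true they are clamped to the edge (resampling semantics).
// [[Rcpp::export]]
arma::mat cc_resize(const arma::mat& img, int oh, int ow, double sy, double sx,
                    double oy, double ox, bool nearest, bool clamp = false) {
  arma::mat out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i)
      out(i, j) = sample_at(img, i * sy + oy, j * sx + ox, nearest, clamp);
  return out;
}

// out(i,j) = img(srcR(i,j), srcC(i,j))
// [[Rcpp::export]]
arma::mat cc_warp(const arma::mat& img, const arma::mat& srcR,
                  const arma::mat& srcC, bool nearest) {
  const int H = srcR.n_rows, W = srcR.n_cols;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_at(img, srcR(i, j), srcC(i, j), nearest);
  return out;
}

// ---------- separable Gaussian blur (clamped edges) ----------
// [[Rcpp::export]]
arma::mat cc_gauss_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int R = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * R + 1);
  for (int t = -R; t <= R; ++t) k(t + R) = std::exp(-0.5 * t * t / (sigma * sigma));
  k /= arma::accu(k);
  const int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -R; t <= R; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        s += k(t + R) * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -R; t <= R; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        s += k(t + R) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// ---------- boundary voxels (6-connectivity) ----------
// [[Rcpp::export]]
arma::cube cc_boundary6(const arma::cube& m) {
  const int H = m.n_rows, W = m.n_cols, D = m.n_slices;
  arma::cube out(H, W, D, arma::fill::zeros);
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (m(i, j, d) <= 0) continue;
        bool bd = (i == 0 || m(i - 1, j, d) <= 0) ||
                  (i == H - 1 || m(i + 1, j, d) <= 0) ||
                  (j == 0 || m(i, j - 1, d) <= 0) ||
                  (j == W - 1 || m(i, j + 1, d) <= 0) ||
                  (d == 0 || m(i, j, d - 1) <= 0) ||
                  (d == D - 1 || m(i, j, d + 1) <= 0);
        if (bd) out(i, j, d) = 1.0;
      }
  return out;
}

// Directed nearest-neighbour distances: for each row of A (points, mm), the
// distance to the closest row of B.
// [[Rcpp::export]]
arma::vec cc_nn_directed(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows, d = A.n_cols;
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        const double t = A(i, k) - B(j, k);
        s += t * t;
      }
      if (s < best) best = s;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
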