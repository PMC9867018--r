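// Low-level numeric kernels: convolution primitives for the tiny CNNs,
// Canny stages with the exact conventions the R layer documents, and
// connectivity-pinned raster ops (4-conn background fill, 4/8-conn labeling).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col: x is (H, W, Cin); output (H*W, k*k*Cin) with zero padding, stride 1,
// "same" output size. Column order matches the column-major layout of an R
// weight array dim (k, k, Cin, Cout): ki fastest, then kj, then channel.
static arma::mat im2col_same(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= H) continue;
            out(i + H * j, q) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add inverse of im2col_same
static arma::cube col2im_same(const arma::mat& m, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += m(i + H * j, q);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::cube& w_flat,
                          const arma::vec& b, int k, int cout) {
  // w_flat is the R weight array reshaped to (k*k*Cin, Cout, 1)
  const int H = x.n_rows, W = x.n_cols;
  arma::mat X = im2col_same(x, k);
  arma::mat Wm(const_cast<double*>(w_flat.memptr()), k * k * x.n_slices, cout, false, true);
  arma::mat O = X * Wm;
  O.each_row() += b.t();
  arma::cube out(H, W, cout);
  for (int c = 0; c < cout; ++c)
    out.slice(c) = arma::reshape(O.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::cube& w_flat,
                    const arma::cube& gout, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::mat X = im2col_same(x, k);
  arma::mat G(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    G.col(c) = arma::vectorise(gout.slice(c));
  arma::mat Wm(const_cast<double*>(w_flat.memptr()), k * k * Cin, Cout, false, true);
  arma::mat gw = X.t() * G;                    // (k*k*Cin, Cout)
  arma::vec gb = arma::sum(G, 0).t();
  arma::cube gx = col2im_same(G * Wm.t(), H, W, Cin, k);
  return List::create(_["gw"] = gw, _["gb"] = gb, _["gx"] = gx);
}

// 2x2 max pooling, stride 2; idx stores the 0-based linear index into the
// input slice of each pooled maximum (first-encountered max wins: ties are
// broken toward the smaller row, then column — deterministic).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  arma::cube out(oh, ow, C);
  arma::ucube idx(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double best = -1e300; unsigned bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, c);
            if (v > best) { best = v; bi = si + H * sj; }
          }
        }
        out(i, j, c) = best; idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gout,
                            int H, int W) {
  const int C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const int oh = gout.n_rows, ow = gout.n_cols;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const unsigned q = idx(i, j, c);
        gx(q % H, q / H, c) += gout(i, j, c);
      }
  }
  return gx;
}

// nearest-neighbour 2x upsampling and its adjoint
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        out(i, j, c) = x(i / 2, j / 2, c);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned j = 0; j < gout.n_cols; ++j)
      for (unsigned i = 0; i < gout.n_rows; ++i)
        gx(i / 2, j / 2, c) += gout(i, j, c);
  return gx;
}

// bilinear resize of a single-channel map, align-corners convention
// [[Rcpp::export]]
arma::mat cpp_bilinear_resize(const arma::mat& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat out(oh, ow);
  const double si = oh > 1 ? double(H - 1) / (oh - 1) : 0.0;
  const double sj = ow > 1 ? double(W - 1) / (ow - 1) : 0.0;
  for (int j = 0; j < ow; ++j) {
    const double fj = j * sj;
    const int j0 = std::min(int(fj), W - 1), j1 = std::min(j0 + 1, W - 1);
    const double wj = fj - j0;
    for (int i = 0; i < oh; ++i) {
      const double fi = i * si;
      const int i0 = std::min(int(fi), H - 1), i1 = std::min(i0 + 1, H - 1);
      const double wi = fi - i0;
      out(i, j) = (1 - wi) * (1 - wj) * x(i0, j0) + wi * (1 - wj) * x(i1, j0)
                + (1 - wi) * wj * x(i0, j1) + wi * wj * x(i1, j1);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Canny stages. Conventions (mirrored by the documentation and the test
// oracle): Gaussian kernel of odd side `ksize` with sigma =
// 0.3*((ksize-1)*0.5 - 1) + 0.8, replicated borders; Sobel 3x3; gradient
// direction quantised to 4 bins; a pixel survives NMS if its magnitude is
// >= both neighbours along the gradient direction; hysteresis links weak
// (>= low) pixels 8-connected to strong (>= high) pixels.

static arma::mat sep_gauss(const arma::mat& x, int ksize) {
  const double sigma = 0.3 * ((ksize - 1) * 0.5 - 1.0) + 0.8;
  const int r = (ksize - 1) / 2;
  arma::vec g(ksize);
  for (int t = -r; t <= r; ++t) g(t + r) = std::exp(-0.5 * t * t / (sigma * sigma));
  g /= arma::accu(g);
  const int H = x.n_rows, W = x.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int si = std::min(std::max(i + t, 0), H - 1);
        s += g(t + r) * x(si, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int sj = std::min(std::max(j + t, 0), W - 1);
        s += g(t + r) * tmp(i, sj);
      }
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_canny(const arma::mat& img, int ksize, double low, double high) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat sm = sep_gauss(img, ksize);
  arma::mat gx(H, W, arma::fill::zeros), gy(H, W, arma::fill::zeros);
  auto at = [&](int i, int j) {
    return sm(std::min(std::max(i, 0), H - 1), std::min(std::max(j, 0), W - 1));
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      // gx: horizontal (column) derivative; gy: vertical (row) derivative
      gx(i, j) = (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1))
               - (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1));
      gy(i, j) = (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1))
               - (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1));
    }
  arma::mat mag = arma::sqrt(gx % gx + gy % gy);
  // non-maximum suppression, 4 direction bins
  arma::mat nms(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double m = mag(i, j);
      if (m < low) continue;
      double ang = std::atan2(gy(i, j), gx(i, j)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int di1, dj1;
      if (ang < 22.5 || ang >= 157.5)      { di1 = 0; dj1 = 1; }   // horizontal gradient
      else if (ang < 67.5)                 { di1 = 1; dj1 = 1; }   // diagonal
      else if (ang < 112.5)                { di1 = 1; dj1 = 0; }   // vertical gradient
      else                                 { di1 = 1; dj1 = -1; }  // anti-diagonal
      auto magat = [&](int a, int b) {
        if (a < 0 || a >= H || b < 0 || b >= W) return 0.0;
        return mag(a, b);
      };
      if (m >= magat(i + di1, j + dj1) && m >= magat(i - di1, j - dj1))
        nms(i, j) = m;
    }
  // hysteresis: BFS from strong pixels through weak ones (8-connected)
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int>> stack;
  std::vector<char> vis(H * W, 0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (nms(i, j) >= high) { stack.push_back({i, j}); vis[i + H * j] = 1; }
  while (!stack.empty()) {
    auto [i, j] = stack.back(); stack.pop_back();
    out(i, j) = true;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int a = i + di, b = j + dj;
        if (a < 0 || a >= H || b < 0 || b >= W || vis[a + H * b]) continue;
        if (nms(a, b) >= low) { vis[a + H * b] = 1; stack.push_back({a, b}); }
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// connected-component labeling; connectivity 4 or 8; labels assigned in
// row-major scan order so label 1 contains the lexicographically smallest
// (row, col) foreground pixel
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int n8i[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int n8j[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int n4i[4] = {-1, 1, 0, 0};
  const int n4j[4] = {0, 0, -1, 1};
  const int nn = connectivity == 8 ? 8 : 4;
  const int* ni = connectivity == 8 ? n8i : n4i;
  const int* nj = connectivity == 8 ? n8j : n4j;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [a, b] = stack.back(); stack.pop_back();
        for (int t = 0; t < nn; ++t) {
          const int p = a + ni[t], q = b + nj[t];
          if (p < 0 || p >= H || q < 0 || q >= W) continue;
          if (mask(p, q) && !lab(p, q)) { lab(p, q) = next; stack.push_back({p, q}); }
        }
      }
    }
  return lab;
}

// pixels 4-connected to the image border through non-blocked pixels
// [[Rcpp::export]]
LogicalMatrix cpp_reach_border(const LogicalMatrix& blocked) {
  const int H = blocked.nrow(), W = blocked.ncol();
  LogicalMatrix reach(H, W);
  std::vector<std::pair<int, int>> stack;
  auto push = [&](int i, int j) {
    if (i < 0 || i >= H || j < 0 || j >= W) return;
    if (blocked(i, j) || reach(i, j)) return;
    reach(i, j) = true; stack.push_back({i, j});
  };
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  while (!stack.empty()) {
    auto [i, j] = stack.back(); stack.pop_back();
    push(i - 1, j); push(i + 1, j); push(i, j - 1); push(i, j + 1);
  }
  return reach;
}
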