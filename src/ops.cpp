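// Low-level array operations for the CPU convolution engine.
//
// Feature maps are R arrays with dim = c(H, W, C) (row = y, col = x,
// slice = channel), which map directly onto arma::cube. Convolution
// weights are R arrays with dim = c(kh, kw, c_in, c_out); their
// column-major flattening is exactly the (kh*kw*c_in) x c_out matrix
// used in the im2col GEMM, so no data is rearranged on the way in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube pad_cube(const arma::cube& x, int pt, int pb, int pl, int pr) {
  if (pt == 0 && pb == 0 && pl == 0 && pr == 0) return x;
  arma::cube xp(x.n_rows + pt + pb, x.n_cols + pl + pr, x.n_slices,
                arma::fill::zeros);
  xp.subcube(pt, pl, 0, pt + x.n_rows - 1, pl + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// im2col for stride-1 convolution, laid out (Ho*Wo) x (kh*kw*cin): column
// r = (dkh, dkw, cin) matches the column-major flattening of the weight
// array, and pixels run contiguously down each column for cache-friendly
// fills and GEMM without transposition.
static arma::mat im2col(const arma::cube& xp, int kh, int kw) {
  const int Ho = xp.n_rows - kh + 1;
  const int Wo = xp.n_cols - kw + 1;
  const int Cin = xp.n_slices;
  arma::mat col((size_t)Ho * Wo, kh * kw * Cin);
  for (int c = 0; c < Cin; ++c) {
    const arma::mat& xs = xp.slice(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        double* dst = col.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const double* src = xs.colptr(wo + dw) + dh;
          std::copy(src, src + Ho, dst + (size_t)wo * Ho);
        }
      }
    }
  }
  return col;
}

static void dims4(const NumericVector& w, int* d) {
  IntegerVector dm = w.attr("dim");
  if (dm.size() != 4) stop("weight array must have 4 dimensions");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericVector cc_conv2d_fwd(const arma::cube& x, const NumericVector& w,
                            const arma::vec& b, const IntegerVector& pad) {
  int d[4];
  dims4(w, d);
  const int kh = d[0], kw = d[1], cin = d[2], cout = d[3];
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  arma::cube xp = pad_cube(x, pad[0], pad[1], pad[2], pad[3]);
  if ((int)xp.n_rows < kh || (int)xp.n_cols < kw)
    stop("input smaller than kernel after padding");
  const int Ho = xp.n_rows - kh + 1, Wo = xp.n_cols - kw + 1;
  arma::mat col = im2col(xp, kh, kw);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * cin, cout,
                     false, true);
  arma::mat Y = col * Wm;               // (Ho*Wo) x cout == cube memory layout
  Y.each_row() += b.t();
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  return out;
}

// [[Rcpp::export]]
List cc_conv2d_bwd(const arma::cube& x, const NumericVector& w,
                   const arma::cube& dy, const IntegerVector& pad,
                   bool need_dx) {
  int d[4];
  dims4(w, d);
  const int kh = d[0], kw = d[1], cin = d[2], cout = d[3];
  arma::cube xp = pad_cube(x, pad[0], pad[1], pad[2], pad[3]);
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const size_t npix = (size_t)Ho * Wo;
  const arma::mat Dy(const_cast<double*>(dy.memptr()), npix, cout, false, true);
  arma::mat col = im2col(xp, kh, kw);
  arma::mat dWm = col.t() * Dy;         // (kh*kw*cin) x cout
  arma::vec db = arma::sum(Dy, 0).t();

  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = IntegerVector::create(kh, kw, cin, cout);

  List out = List::create(Named("dw") = dw, Named("db") = db);
  if (need_dx) {
    const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * cin, cout,
                       false, true);
    arma::mat dcol = Dy * Wm.t();       // npix x (kh*kw*cin)
    arma::cube dxp(xp.n_rows, xp.n_cols, cin, arma::fill::zeros);
    for (int c = 0; c < cin; ++c) {
      arma::mat& dxs = dxp.slice(c);
      for (int dw_ = 0; dw_ < kw; ++dw_) {
        for (int dh = 0; dh < kh; ++dh) {
          const int r = dh + kh * (dw_ + kw * c);
          const double* src = dcol.colptr(r);
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = dxs.colptr(wo + dw_) + dh;
            const double* s2 = src + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) dst[ho] += s2[ho];
          }
        }
      }
    }
    arma::cube dx = dxp.subcube(pad[0], pad[2], 0,
                                pad[0] + x.n_rows - 1,
                                pad[2] + x.n_cols - 1, cin - 1);
    out["dx"] = dx;
  }
  return out;
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled values
// and the flat (within-slice, column-major) index of each argmax.
// [[Rcpp::export]]
List cc_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = xs(2 * ho, 2 * wo);
        int bi = 2 * ho, bj = 2 * wo;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = xs(2 * ho + di, 2 * wo + dj);
            if (v > best) { best = v; bi = 2 * ho + di; bj = 2 * wo + dj; }
          }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = bi + H * bj;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cc_maxpool2_bwd(const arma::icube& idx, const arma::cube& dy,
                           int H, int W) {
  const int C = dy.n_slices, Ho = dy.n_rows, Wo = dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dxs = dx.slice_memptr(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        dxs[idx(ho, wo, c)] += dy(ho, wo, c);
  }
  return dx;
}

// Bilinear 2x upsampling (half-pixel centers, edges clamped): output pixel
// i samples the input at i/2 - 0.25.
static void up2_coeffs(int n, arma::ivec& i0, arma::ivec& i1, arma::vec& w1) {
  i0.set_size(2 * n); i1.set_size(2 * n); w1.set_size(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    const double s = 0.5 * i - 0.25;
    int lo = (int)std::floor(s);
    double w = s - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; }
    if (hi > n - 1) { hi = n - 1; }
    if (lo > n - 1) { lo = n - 1; }
    i0[i] = lo; i1[i] = hi; w1[i] = w;
  }
}

// [[Rcpp::export]]
arma::cube cc_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::ivec r0, r1, c0, c1; arma::vec wr, wc;
  up2_coeffs(H, r0, r1, wr);
  up2_coeffs(W, c0, c1, wc);
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    arma::mat& ys = y.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      for (int i = 0; i < 2 * H; ++i) {
        ys(i, j) =
          (1 - wr[i]) * ((1 - wc[j]) * xs(r0[i], c0[j]) + wc[j] * xs(r0[i], c1[j])) +
          wr[i]       * ((1 - wc[j]) * xs(r1[i], c0[j]) + wc[j] * xs(r1[i], c1[j]));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cc_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::ivec r0, r1, c0, c1; arma::vec wr, wc;
  up2_coeffs(H, r0, r1, wr);
  up2_coeffs(W, c0, c1, wc);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& ds = dy.slice(c);
    arma::mat& dxs = dx.slice(c);
    for (int j = 0; j < 2 * W; ++j) {
      for (int i = 0; i < 2 * H; ++i) {
        const double g = ds(i, j);
        dxs(r0[i], c0[j]) += (1 - wr[i]) * (1 - wc[j]) * g;
        dxs(r0[i], c1[j]) += (1 - wr[i]) * wc[j] * g;
        dxs(r1[i], c0[j]) += wr[i] * (1 - wc[j]) * g;
        dxs(r1[i], c1[j]) += wr[i] * wc[j] * g;
      }
    }
  }
  return dx;
}

// 8-connected component labeling of a binary matrix (two-pass union-find).
// Labels are compacted to 1..n in raster (column-major) discovery order.
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      const int ni[4] = { i - 1, i - 1, i, i + 1 };   // N, NW-ish in col-major scan:
      const int nj[4] = { j, j - 1, j - 1, j - 1 };   // up, up-left, left, down-left
      for (int k = 0; k < 4; ++k) {
        if (ni[k] < 0 || ni[k] >= H || nj[k] < 0) continue;
        const int l = lab(ni[k], nj[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = parent.size();
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j)) {
        const int r = find(lab(i, j));
        if (!remap[r]) remap[r] = ++next;
        lab(i, j) = remap[r];
      }
  return lab;
}
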