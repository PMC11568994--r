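// Numerical kernels: convolution (im2col + GEMM) with analytic backward,
// 2x2 pooling / upsampling, bilinear projective warping, vessel stroke
// rendering, and the RANSAC-over-DLT inner loop.
//
// Conventions (shared with the R side):
//   * rasters are arma::cube (H rows, W cols, C slices), values double;
//   * pixel coordinates are 0-based with x = column, y = row, pixel centres
//     at integer coordinates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a square kernel of size k, dilation d, stride 1, 'same' zero
// padding.  Row p = pixel (y = p %% H, x = p / H, column-major like R),
// columns ordered (channel, ky, kx).
static arma::mat im2col(const arma::cube &x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = d * (k - 1) / 2;
  arma::mat M(H * (long long)W, (long long)k * k * C, arma::fill::zeros);
  long long col = 0;
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx, ++col) {
        const int oy = ky * d - pad, ox = kx * d - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(W, W - ox);
        for (int xx = x0; xx < x1; ++xx) {
          double *dst = M.colptr(col) + (long long)xx * H + y0;
          const double *src = x.slice_colptr(c, xx + ox) + (y0 + oy);
          std::copy(src, src + (y1 - y0), dst);
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add columns back into an H x W x C cube.
static arma::cube col2im(const arma::mat &M, int H, int W, int C,
                         int k, int d) {
  const int pad = d * (k - 1) / 2;
  arma::cube x(H, W, C, arma::fill::zeros);
  long long col = 0;
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx, ++col) {
        const int oy = ky * d - pad, ox = kx * d - pad;
        const int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(W, W - ox);
        for (int xx = x0; xx < x1; ++xx) {
          const double *src = M.colptr(col) + (long long)xx * H + y0;
          double *dst = x.slice_colptr(c, xx + ox) + (y0 + oy);
          for (int i = 0; i < y1 - y0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube &x, const arma::mat &W,
                          const arma::rowvec &b, int k, int d) {
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  arma::mat y = im2col(x, k, d) * W;
  y.each_row() += b;
  arma::cube out(y.memptr(), H, Wd, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube &x, const arma::mat &W,
                    const arma::cube &gy, int k, int d, bool need_gx) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat M = im2col(x, k, d);
  arma::mat gym(const_cast<double *>(gy.memptr()), (long long)H * Wd, Cout,
                false, true);
  arma::mat gW = M.t() * gym;
  arma::rowvec gb = arma::sum(gym, 0);
  List out = List::create(Named("gW") = gW, Named("gb") = gb);
  if (need_gx) {
    arma::mat gM = gym * W.t();
    out["gx"] = col2im(gM, H, Wd, C, k, d);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube &x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube y(H, W, C);
  arma::ucube idx(H, W, C); // winner offset 0..3 = (dy, dx) in 2x2 block
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = x(2 * i, 2 * j, c);
        unsigned bi = 0;
        const int dy[4] = {0, 1, 0, 1}, dx[4] = {0, 0, 1, 1};
        for (unsigned q = 1; q < 4; ++q) {
          double v = x(2 * i + dy[q], 2 * j + dx[q], c);
          if (v > best) { best = v; bi = q; }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube &gy, const arma::ucube &idx) {
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  arma::cube gx(2 * H, 2 * W, C, arma::fill::zeros);
  const int dy[4] = {0, 1, 0, 1}, dx[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        unsigned q = idx(i, j, c);
        gx(2 * i + dy[q], 2 * j + dx[q], c) = gy(i, j, c);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube &gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// Inverse-mapping bilinear warp: out(y, x) = in(Hinv * (x, y, 1)).
// Out-of-frame samples take `fill`.
// [[Rcpp::export]]
arma::cube cpp_warp_projective(const arma::cube &x, const arma::mat &Hinv,
                               int outH, int outW, double fill) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(outH, outW, C);
  y.fill(fill);
  for (int c2 = 0; c2 < outW; ++c2)
    for (int r = 0; r < outH; ++r) {
      const double w = Hinv(2, 0) * c2 + Hinv(2, 1) * r + Hinv(2, 2);
      if (std::abs(w) < 1e-12) continue;
      const double xs = (Hinv(0, 0) * c2 + Hinv(0, 1) * r + Hinv(0, 2)) / w;
      const double ys = (Hinv(1, 0) * c2 + Hinv(1, 1) * r + Hinv(1, 2)) / w;
      if (xs < 0 || ys < 0 || xs > W - 1 || ys > H - 1) continue;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = xs - x0, fy = ys - y0;
      for (int c = 0; c < C; ++c) {
        const double v =
            (1 - fy) * ((1 - fx) * x(y0, x0, c) + fx * x(y0, x1, c)) +
            fy * ((1 - fx) * x(y1, x0, c) + fx * x(y1, x1, c));
        y(r, c2, c) = v;
      }
    }
  return y;
}

// Soft anti-aliased stroke rendering: samples is n x 3 (x, y, halfwidth);
// the returned H x W plane is the max over samples of
// clamp(halfwidth + 0.5 - distance, 0, 1).
// [[Rcpp::export]]
arma::mat cpp_render_strokes(int H, int W, const arma::mat &samples) {
  arma::mat plane(H, W, arma::fill::zeros);
  for (arma::uword s = 0; s < samples.n_rows; ++s) {
    const double xc = samples(s, 0), yc = samples(s, 1), hw = samples(s, 2);
    const int r0 = std::max(0, (int)std::floor(yc - hw - 1.0));
    const int r1 = std::min(H - 1, (int)std::ceil(yc + hw + 1.0));
    const int c0 = std::max(0, (int)std::floor(xc - hw - 1.0));
    const int c1 = std::min(W - 1, (int)std::ceil(xc + hw + 1.0));
    for (int cc = c0; cc <= c1; ++cc)
      for (int rr = r0; rr <= r1; ++rr) {
        const double dist = std::hypot(cc - xc, rr - yc);
        const double v = std::min(1.0, std::max(0.0, hw + 0.5 - dist));
        if (v > plane(rr, cc)) plane(rr, cc) = v;
      }
  }
  return plane;
}

// Separable correlation with a symmetric 1-D kernel, replicate padding.
// [[Rcpp::export]]
arma::cube cpp_sepconv(const arma::cube &x, const arma::vec &kern) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int r = (kern.n_elem - 1) / 2;
  arma::cube tmp(H, W, C), y(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int ii = std::min(H - 1, std::max(0, i + t));
          acc += kern(t + r) * x(ii, j, c);
        }
        tmp(i, j, c) = acc;
      }
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int jj = std::min(W - 1, std::max(0, j + t));
          acc += kern(t + r) * tmp(i, jj, c);
        }
        y(i, j, c) = acc;
      }
  }
  return y;
}

// --- Homography estimation -------------------------------------------------

// Similarity normalization (centroid at origin, mean distance sqrt(2)).
static arma::mat33 norm_transform(const arma::mat &pts) {
  arma::rowvec c = arma::mean(pts, 0);
  double md = arma::mean(arma::sqrt(arma::square(pts.col(0) - c(0)) +
                                    arma::square(pts.col(1) - c(1))));
  double s = md > 1e-12 ? std::sqrt(2.0) / md : 1.0;
  arma::mat33 T = arma::eye(3, 3);
  T(0, 0) = s; T(1, 1) = s; T(0, 2) = -s * c(0); T(1, 2) = -s * c(1);
  return T;
}

// Normalized DLT from point rows (x, y) -> (x', y'); empty on failure.
static arma::mat dlt(const arma::mat &src, const arma::mat &dst) {
  const int n = src.n_rows;
  arma::mat33 Ts = norm_transform(src), Td = norm_transform(dst);
  arma::mat A(2 * n, 9, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const double x = Ts(0, 0) * src(i, 0) + Ts(0, 2);
    const double y = Ts(1, 1) * src(i, 1) + Ts(1, 2);
    const double u = Td(0, 0) * dst(i, 0) + Td(0, 2);
    const double v = Td(1, 1) * dst(i, 1) + Td(1, 2);
    A(2 * i, 0) = -x; A(2 * i, 1) = -y; A(2 * i, 2) = -1;
    A(2 * i, 6) = u * x; A(2 * i, 7) = u * y; A(2 * i, 8) = u;
    A(2 * i + 1, 3) = -x; A(2 * i + 1, 4) = -y; A(2 * i + 1, 5) = -1;
    A(2 * i + 1, 6) = v * x; A(2 * i + 1, 7) = v * y; A(2 * i + 1, 8) = v;
  }
  // full SVD: for a minimal (8x9) system the null vector is the 9th right
  // singular vector, which economy SVD would drop
  arma::mat U, V;
  arma::vec sv;
  if (!arma::svd(U, sv, V, A, "std")) return arma::mat();
  arma::vec h = V.col(V.n_cols - 1);
  arma::mat33 Hn(arma::reshape(h, 3, 3).t());
  arma::mat33 H = arma::inv(Td) * Hn * Ts;
  if (std::abs(H(2, 2)) > 1e-12) H /= H(2, 2);
  return H;
}

// [[Rcpp::export]]
arma::mat cpp_dlt(const arma::mat &src, const arma::mat &dst) {
  return dlt(src, dst);
}

static arma::vec reproj_errors(const arma::mat &H, const arma::mat &src,
                               const arma::mat &dst) {
  const int n = src.n_rows;
  arma::vec e(n);
  for (int i = 0; i < n; ++i) {
    const double w = H(2, 0) * src(i, 0) + H(2, 1) * src(i, 1) + H(2, 2);
    if (std::abs(w) < 1e-12) { e(i) = arma::datum::inf; continue; }
    const double u = (H(0, 0) * src(i, 0) + H(0, 1) * src(i, 1) + H(0, 2)) / w;
    const double v = (H(1, 0) * src(i, 0) + H(1, 1) * src(i, 1) + H(1, 2)) / w;
    e(i) = std::hypot(u - dst(i, 0), v - dst(i, 1));
  }
  return e;
}

// [[Rcpp::export]]
arma::vec cpp_reproj_errors(const arma::mat &H, const arma::mat &src,
                            const arma::mat &dst) {
  return reproj_errors(H, src, dst);
}

static bool degenerate4(const arma::mat &p) {
  // any 3 of the 4 points (near-)collinear
  for (int a = 0; a < 4; ++a)
    for (int b = a + 1; b < 4; ++b)
      for (int c = b + 1; c < 4; ++c) {
        const double area =
            std::abs((p(b, 0) - p(a, 0)) * (p(c, 1) - p(a, 1)) -
                     (p(c, 0) - p(a, 0)) * (p(b, 1) - p(a, 1)));
        if (area < 1e-8) return true;
      }
  return false;
}

// RANSAC scoring loop over pre-drawn (or exhaustive) 4-point samples.
// samples: S x 4 matrix of 0-based row indices into src/dst.
// Returns the best hypothesis by inlier count (ties: smaller mean inlier
// error, then the earlier sample — deterministic).
// [[Rcpp::export]]
List cpp_ransac(const arma::mat &src, const arma::mat &dst,
                const arma::umat &samples, double thresh) {
  const int M = src.n_rows;
  int best_count = -1;
  double best_score = arma::datum::inf;
  arma::mat bestH;
  arma::uvec best_inl(M, arma::fill::zeros);
  for (arma::uword s = 0; s < samples.n_rows; ++s) {
    arma::uvec id = samples.row(s).t();
    arma::mat ps = src.rows(id), pd = dst.rows(id);
    if (degenerate4(ps) || degenerate4(pd)) continue;
    arma::mat H = dlt(ps, pd);
    if (H.n_elem == 0 || !H.is_finite()) continue;
    arma::vec e = reproj_errors(H, src, dst);
    arma::uvec inl = (e < thresh);
    int cnt = arma::accu(inl);
    double score = cnt > 0 ? arma::accu(e % arma::conv_to<arma::vec>::from(inl)) / cnt
                           : arma::datum::inf;
    if (cnt > best_count || (cnt == best_count && score < best_score)) {
      best_count = cnt;
      best_score = score;
      bestH = H;
      best_inl = inl;
    }
  }
  return List::create(Named("H") = bestH, Named("inliers") = best_inl,
                      Named("count") = best_count);
}

// Valid-mode patch pipeline: no padding, each 3x3 layer shrinks the map by
// 2*dilation per side, so a receptive-field patch collapses to exactly the
// centre pixel at the output.  With zero-filled patch extraction this equals
// 'same'-padded dense evaluation at the centre, at a fraction of the cost.
// Patches are processed one at a time (cache-sized working sets) in single
// precision: descriptor training tolerates float rounding and gains the
// bandwidth back.
static arma::fmat im2col_valid_f(const arma::fcube &x, int k, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oH = H - d * (k - 1), oW = W - d * (k - 1);
  arma::fmat M((long long)oH * oW, (long long)k * k * C);
  long long col = 0;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx, ++col)
        for (int xx = 0; xx < oW; ++xx) {
          const float *src = x.slice_colptr(c, xx + kx * d) + ky * d;
          std::copy(src, src + oH, M.colptr(col) + (long long)xx * oH);
        }
  return M;
}

static arma::fcube col2im_valid_f(const arma::fmat &M, int H, int W, int C,
                                  int k, int d) {
  const int oH = H - d * (k - 1), oW = W - d * (k - 1);
  arma::fcube x(H, W, C, arma::fill::zeros);
  long long col = 0;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx, ++col)
        for (int xx = 0; xx < oW; ++xx) {
          const float *src = M.colptr(col) + (long long)xx * oH;
          float *dst = x.slice_colptr(c, xx + kx * d) + ky * d;
          for (int i = 0; i < oH; ++i) dst[i] += src[i];
        }
  return x;
}

// [[Rcpp::export]]
List cpp_patch_forward_valid(const List &patches, const List &Ws,
                             const List &bs, const IntegerVector &ks,
                             const IntegerVector &ds) {
  const int P = patches.size(), L = Ws.size();
  std::vector<arma::fmat> Wf(L);
  std::vector<arma::frowvec> bf(L);
  for (int l = 0; l < L; ++l) {
    Wf[l] = arma::conv_to<arma::fmat>::from(as<arma::mat>(Ws[l]));
    bf[l] = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bs[l]));
  }
  List acts(P);
  arma::mat centers;
  for (int p = 0; p < P; ++p) {
    arma::fcube h =
        arma::conv_to<arma::fcube>::from(as<arma::cube>(patches[p]));
    List layer_in(L);
    for (int l = 0; l < L; ++l) {
      layer_in[l] = h;
      const int oH = h.n_rows - ds[l] * (ks[l] - 1);
      const int oW = h.n_cols - ds[l] * (ks[l] - 1);
      arma::fmat y = im2col_valid_f(h, ks[l], ds[l]) * Wf[l];
      y.each_row() += bf[l];
      arma::fcube out(y.memptr(), oH, oW, Wf[l].n_cols);
      if (l < L - 1) out.transform([](float v) { return v > 0 ? v : 0.0f; });
      h = out;
    }
    if (p == 0) centers.set_size(P, h.n_slices);
    const int cy = h.n_rows / 2, cx = h.n_cols / 2;
    for (arma::uword c = 0; c < h.n_slices; ++c) centers(p, c) = h(cy, cx, c);
    acts[p] = List::create(Named("in") = layer_in,
                           Named("oh") = (int)h.n_rows,
                           Named("ow") = (int)h.n_cols);
  }
  return List::create(Named("centers") = centers, Named("acts") = acts);
}

// [[Rcpp::export]]
List cpp_patch_backward_valid(const List &fw, const List &Ws,
                              const IntegerVector &ks,
                              const IntegerVector &ds,
                              const arma::mat &gcenters) {
  List acts = fw["acts"];
  const int P = acts.size(), L = Ws.size();
  std::vector<arma::fmat> Wf(L), gW(L);
  std::vector<arma::frowvec> gb(L);
  for (int l = 0; l < L; ++l) {
    Wf[l] = arma::conv_to<arma::fmat>::from(as<arma::mat>(Ws[l]));
    gW[l].zeros(Wf[l].n_rows, Wf[l].n_cols);
    gb[l].zeros(Wf[l].n_cols);
  }
  arma::fmat gc = arma::conv_to<arma::fmat>::from(gcenters);
  for (int p = 0; p < P; ++p) {
    List ap = acts[p];
    List layer_in = ap["in"];
    const int oh = ap["oh"], ow = ap["ow"];
    arma::fcube g(oh, ow, Wf[L - 1].n_cols, arma::fill::zeros);
    for (arma::uword c = 0; c < g.n_slices; ++c)
      g(oh / 2, ow / 2, c) = gc(p, c);
    for (int l = L - 1; l >= 0; --l) {
      arma::fcube x = as<arma::fcube>(layer_in[l]);
      arma::fmat M = im2col_valid_f(x, ks[l], ds[l]);
      arma::fmat gym(g.memptr(), (long long)g.n_rows * g.n_cols, g.n_slices,
                     false, true);
      gW[l] += M.t() * gym;
      gb[l] += arma::sum(gym, 0);
      if (l > 0) {
        arma::fmat gM = gym * Wf[l].t();
        arma::fcube gx = col2im_valid_f(gM, x.n_rows, x.n_cols, x.n_slices,
                                        ks[l], ds[l]);
        // ReLU mask: layer l's input is layer l-1's post-ReLU output
        for (arma::uword q = 0; q < gx.n_elem; ++q)
          if (x(q) <= 0) gx(q) = 0;
        g = gx;
      }
    }
  }
  List outW(L), outb(L);
  for (int l = 0; l < L; ++l) {
    outW[l] = arma::conv_to<arma::mat>::from(gW[l]);
    outb[l] = arma::conv_to<arma::rowvec>::from(gb[l]);
  }
  return List::create(Named("gW") = outW, Named("gb") = outb);
}

// Global HSV shift of an RGB [0,1] cube: hue wraps, saturation and value
// clamp.  Matches the standard hexcone conversion.
// [[Rcpp::export]]
arma::cube cpp_hsv_shift(const arma::cube &img, double dh, double ds,
                         double dv) {
  arma::cube out(img.n_rows, img.n_cols, 3);
  const long long n = (long long)img.n_rows * img.n_cols;
  const double *r = img.slice_colptr(0, 0), *g = img.slice_colptr(1, 0),
               *b = img.slice_colptr(2, 0);
  double *ro = out.slice_colptr(0, 0), *go = out.slice_colptr(1, 0),
         *bo = out.slice_colptr(2, 0);
  for (long long i = 0; i < n; ++i) {
    const double mx = std::max(r[i], std::max(g[i], b[i]));
    const double mn = std::min(r[i], std::min(g[i], b[i]));
    const double delta = mx - mn;
    double h = 0;
    if (delta > 0) {
      if (mx == r[i]) { h = (g[i] - b[i]) / delta; h -= 6.0 * std::floor(h / 6.0); }
      else if (mx == g[i]) h = (b[i] - r[i]) / delta + 2.0;
      else h = (r[i] - g[i]) / delta + 4.0;
      h /= 6.0;
      if (h < 0) h += 1.0;
    }
    double s = mx > 0 ? delta / mx : 0.0;
    double v = mx;
    h += dh; h -= std::floor(h);
    s = std::min(1.0, std::max(0.0, s + ds));
    v = std::min(1.0, std::max(0.0, v + dv));
    const double hh = h * 6.0;
    const int sx = std::min(5, (int)std::floor(hh));
    const double f = hh - std::floor(hh);
    const double p = v * (1 - s), q = v * (1 - s * f),
                 t = v * (1 - s * (1 - f));
    switch (sx) {
      case 0: ro[i] = v; go[i] = t; bo[i] = p; break;
      case 1: ro[i] = q; go[i] = v; bo[i] = p; break;
      case 2: ro[i] = p; go[i] = v; bo[i] = t; break;
      case 3: ro[i] = p; go[i] = q; bo[i] = v; break;
      case 4: ro[i] = t; go[i] = p; bo[i] = v; break;
      default: ro[i] = v; go[i] = p; bo[i] = q; break;
    }
  }
  return out;
}

// Per-channel standardization (zero mean, unit sd with n-1 denominator,
// matching stats::sd) of an H x W x C raster.
// [[Rcpp::export]]
arma::cube cpp_standardize(const arma::cube &x) {
  arma::cube y(x.n_rows, x.n_cols, x.n_slices);
  const long long n = (long long)x.n_rows * x.n_cols;
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    const double *p = x.slice_colptr(c, 0);
    double s = 0, s2 = 0;
    for (long long i = 0; i < n; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    const double m = s / n;
    const double sd = std::sqrt(std::max(0.0, (s2 - n * m * m) / (n - 1)));
    double *q = y.slice_colptr(c, 0);
    const double inv = 1.0 / (sd + 1e-6);
    for (long long i = 0; i < n; ++i) q[i] = (p[i] - m) * inv;
  }
  return y;
}
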