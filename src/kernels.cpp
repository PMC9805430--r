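// Low-level numeric kernels for the segmentation network and its
// deconvnet inversion. Feature maps are arma::cube (height x width x channels);
// k x k convolutions use 'same' zero padding and an im2col + GEMM layout with
// patch index ci*k*k + dj*k + di (row offset fastest), matching the weight
// matrices of shape (k*k*Cin) x Cout built on the R side.
//
// The modular double-precision entry points (cpp_conv2d_*, cpp_maxpool2_fwd,
// cpp_unpool2, cpp_upconv2_*) back the R-level forward/backward composition
// used for prediction and deconvnet reconstruction. cpp_unet_grad fuses the
// whole training step (forward + Dice/BCE loss + backward) in one call and
// can run in single precision; it mirrors the R composition exactly and is
// cross-checked against it in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

template <typename eT>
static Mat<eT> im2col_t(const Cube<eT>& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = k / 2;
  Mat<eT> P(H * (long long)W, (long long)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const Mat<eT>& sl = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        // input coords: (i + di - pad, j + dj - pad) for output pixel (i, j)
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        const int j0 = std::max(0, pad - dj), j1 = std::min(W, W + pad - dj);
        for (int j = j0; j < j1; ++j) {
          eT* dst = P.colptr(col) + (long long)j * H;
          const eT* src = sl.colptr(j + dj - pad) + (i0 + di - pad);
          std::copy(src, src + (i1 - i0), dst + i0);
        }
      }
    }
  }
  return P;
}

template <typename eT>
static Cube<eT> col2im_t(const Mat<eT>& dP, int H, int W, int C, int k) {
  const int pad = k / 2;
  Cube<eT> dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    Mat<eT>& sl = dx.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        const int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
        const int j0 = std::max(0, pad - dj), j1 = std::min(W, W + pad - dj);
        for (int j = j0; j < j1; ++j) {
          eT* dst = sl.colptr(j + dj - pad) + (i0 + di - pad);
          const eT* src = dP.colptr(col) + (long long)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return dx;
}

template <typename eT>
static Mat<eT> strided_slice_t(const Cube<eT>& dy, int di, int dj) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  Mat<eT> G((long long)H * W, C);
  for (int c = 0; c < C; ++c) {
    const Mat<eT>& sl = dy.slice(c);
    for (int j = 0; j < W; ++j) {
      eT* dst = G.colptr(c) + (long long)j * H;
      const eT* src = sl.colptr(2 * j + dj) + di;
      for (int i = 0; i < H; ++i) dst[i] = src[2 * i];
    }
  }
  return G;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k) {
  mat P = im2col_t(x, k);
  mat out = P * w;
  out.each_row() += b.t();
  cube y(out.memptr(), x.n_rows, x.n_cols, w.n_cols);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat P = im2col_t(x, k);
  mat G(const_cast<double*>(dy.memptr()), (long long)H * W, dy.n_slices,
        false, true);
  mat dW = P.t() * G;
  vec db = sum(G, 0).t();
  mat dP = G * w.t();
  cube dx = col2im_t(dP, H, W, C, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// Deconvnet reverse of a forward convolution: shared weights, no bias.
// Identical to the gradient of the forward output w.r.t. its input.
// [[Rcpp::export]]
arma::cube cpp_conv2d_rev(const arma::cube& sig, const arma::mat& w, int k,
                          int cin) {
  mat G(const_cast<double*>(sig.memptr()),
        (long long)sig.n_rows * sig.n_cols, sig.n_slices, false, true);
  mat dP = G * w.t();
  return col2im_t(dP, (int)sig.n_rows, (int)sig.n_cols, cin, k);
}

// 2x2 max pooling with stride 2; switches record the 0-based linear index
// (within the full input cube) of each pooled maximum.
template <typename eT>
static void pool_fwd_t(const Cube<eT>& x, Cube<eT>& y, uvec& sw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  y.set_size(Ho, Wo, C);
  sw.set_size((long long)Ho * Wo * C);
  long long q = 0;
  for (int c = 0; c < C; ++c) {
    const Mat<eT>& sl = x.slice(c);
    const long long base = (long long)c * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int r = 2 * i, cc = 2 * j;
        eT best = sl(r, cc);
        long long arg = base + (long long)cc * H + r;
        const int dr[3] = {1, 0, 1}, dc[3] = {0, 1, 1};
        for (int t = 0; t < 3; ++t) {
          eT v = sl(r + dr[t], cc + dc[t]);
          if (v > best) {
            best = v;
            arg = base + (long long)(cc + dc[t]) * H + (r + dr[t]);
          }
        }
        y(i, j, c) = best;
        sw[q++] = (unsigned long long)arg;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  cube y;
  uvec sw;
  pool_fwd_t(x, y, sw);
  Rcpp::IntegerVector swi(sw.n_elem);
  for (long long q = 0; q < (long long)sw.n_elem; ++q) swi[q] = (int)sw[q];
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("switches") = swi);
}

// Max unpooling: place each pooled value at its recorded switch location,
// zero elsewhere. Also serves as the pooling gradient.
// [[Rcpp::export]]
arma::cube cpp_unpool2(const arma::cube& p, const Rcpp::IntegerVector& sw,
                       int H, int W) {
  cube y(H, W, p.n_slices, fill::zeros);
  const double* src = p.memptr();
  double* dst = y.memptr();
  const long long n = (long long)p.n_elem;
  for (long long q = 0; q < n; ++q) dst[sw[q]] = src[q];
  return y;
}

// 2x2 stride-2 up-convolution (transposed convolution). Weights as a
// (4*Cin) x Cout matrix with block order (di, dj) in {(0,0),(1,0),(0,1),(1,1)},
// each block Cin x Cout.
template <typename eT>
static Cube<eT> upconv_fwd_t(const Cube<eT>& x, const Mat<eT>& w,
                             const Col<eT>& b) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  Mat<eT> X(const_cast<eT*>(x.memptr()), (long long)H * W, Cin, false, true);
  Cube<eT> y(2 * H, 2 * W, Cout);
  for (int t = 0; t < 4; ++t) {
    const int di = t % 2, dj = t / 2;
    Mat<eT> O = X * w.rows(t * Cin, (t + 1) * Cin - 1);
    O.each_row() += b.t();
    for (int c = 0; c < Cout; ++c) {
      Mat<eT>& sl = y.slice(c);
      for (int j = 0; j < W; ++j) {
        eT* dst = sl.colptr(2 * j + dj) + di;
        const eT* src = O.colptr(c) + (long long)j * H;
        for (int i = 0; i < H; ++i) dst[2 * i] = src[i];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upconv2_fwd(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b) {
  return upconv_fwd_t(x, w, b);
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv2_bwd(const arma::cube& x, const arma::mat& w,
                           const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  mat X(const_cast<double*>(x.memptr()), (long long)H * W, Cin, false, true);
  mat dW(w.n_rows, w.n_cols, fill::zeros);
  vec db(w.n_cols, fill::zeros);
  mat dX((long long)H * W, Cin, fill::zeros);
  for (int t = 0; t < 4; ++t) {
    mat G = strided_slice_t(dy, t % 2, t / 2);
    dW.rows(t * Cin, (t + 1) * Cin - 1) = X.t() * G;
    db += sum(G, 0).t();
    dX += G * w.rows(t * Cin, (t + 1) * Cin - 1).t();
  }
  cube dx(dX.memptr(), H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// Deconvnet reverse of the up-convolution (shared weights, no bias):
// maps a (2H, 2W, Cout) signal back to (H, W, Cin).
// [[Rcpp::export]]
arma::cube cpp_upconv2_rev(const arma::cube& sig, const arma::mat& w,
                           int cin) {
  const int H = sig.n_rows / 2, W = sig.n_cols / 2;
  mat R((long long)H * W, cin, fill::zeros);
  for (int t = 0; t < 4; ++t) {
    mat G = strided_slice_t(sig, t % 2, t / 2);
    R += G * w.rows(t * cin, (t + 1) * cin - 1).t();
  }
  cube out(R.memptr(), H, W, cin);
  return out;
}

// ---------------------------------------------------------------------------
// Fused training step.

template <typename eT>
struct ConvGradT { Mat<eT> dW; Col<eT> db; };

template <typename eT>
static Cube<eT> conv_fwd(const Cube<eT>& x, const Mat<eT>& w,
                         const Col<eT>& b, int k, Mat<eT>& P) {
  P = im2col_t(x, k);
  Mat<eT> out = P * w;
  out.each_row() += b.t();
  return Cube<eT>(out.memptr(), x.n_rows, x.n_cols, w.n_cols);
}

template <typename eT>
static Cube<eT> conv_bwd(const Mat<eT>& P, const Mat<eT>& w,
                         const Cube<eT>& dy, int H, int W, int C, int k,
                         ConvGradT<eT>& g) {
  Mat<eT> G(const_cast<eT*>(dy.memptr()), (long long)H * W, dy.n_slices,
            false, true);
  g.dW = P.t() * G;
  g.db = sum(G, 0).t();
  Mat<eT> dP = G * w.t();
  return col2im_t(dP, H, W, C, k);
}

template <typename eT>
struct BlockWST {
  Cube<eT> x, z1, a1, z2, out;
  Mat<eT> P1, P2;
};

template <typename eT>
static void blk_fwd(const Cube<eT>& x, const Mat<eT>& w1, const Col<eT>& b1,
                    const Mat<eT>& w2, const Col<eT>& b2, int k,
                    BlockWST<eT>& ws) {
  ws.x = x;
  ws.z1 = conv_fwd(x, w1, b1, k, ws.P1);
  ws.a1 = clamp(ws.z1, eT(0), std::numeric_limits<eT>::infinity());
  ws.z2 = conv_fwd(ws.a1, w2, b2, k, ws.P2);
  ws.out = clamp(ws.z2, eT(0), std::numeric_limits<eT>::infinity());
}

template <typename eT>
static Cube<eT> blk_bwd(const Cube<eT>& dout, const BlockWST<eT>& ws,
                        const Mat<eT>& w1, const Mat<eT>& w2, int k,
                        ConvGradT<eT>& g1, ConvGradT<eT>& g2) {
  Cube<eT> dz2 = dout % conv_to<Cube<eT>>::from(ws.z2 > eT(0));
  Cube<eT> da1 = conv_bwd(ws.P2, w2, dz2, ws.a1.n_rows, ws.a1.n_cols,
                          ws.a1.n_slices, k, g2);
  Cube<eT> dz1 = da1 % conv_to<Cube<eT>>::from(ws.z1 > eT(0));
  return conv_bwd(ws.P1, w1, dz1, ws.x.n_rows, ws.x.n_cols, ws.x.n_slices,
                  k, g1);
}

template <typename eT>
static Cube<eT> pool_bwd(const Cube<eT>& dy, const uvec& sw, int H, int W) {
  Cube<eT> dx(H, W, dy.n_slices, fill::zeros);
  const eT* src = dy.memptr();
  eT* dst = dx.memptr();
  for (long long q = 0; q < (long long)dy.n_elem; ++q) dst[sw[q]] = src[q];
  return dx;
}

template <typename eT>
static Cube<eT> upconv_bwd(const Cube<eT>& x, const Mat<eT>& w,
                           const Cube<eT>& dy, ConvGradT<eT>& g) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  Mat<eT> X(const_cast<eT*>(x.memptr()), (long long)H * W, Cin, false, true);
  g.dW.zeros(w.n_rows, w.n_cols);
  g.db.zeros(w.n_cols);
  Mat<eT> dX((long long)H * W, Cin, fill::zeros);
  for (int t = 0; t < 4; ++t) {
    Mat<eT> G = strided_slice_t(dy, t % 2, t / 2);
    g.dW.rows(t * Cin, (t + 1) * Cin - 1) = X.t() * G;
    g.db += sum(G, 0).t();
    dX += G * w.rows(t * Cin, (t + 1) * Cin - 1).t();
  }
  return Cube<eT>(dX.memptr(), H, W, Cin);
}

template <typename eT>
static Rcpp::List grad_pair(const ConvGradT<eT>& g) {
  return Rcpp::List::create(
    Rcpp::Named("w") = conv_to<mat>::from(g.dW),
    Rcpp::Named("b") = conv_to<vec>::from(g.db));
}

template <typename eT>
static Rcpp::List unet_grad_impl(const arma::mat& x, const arma::mat& y,
                                 const Rcpp::List& params, int depth, int k) {
  Rcpp::List encP = params["enc"], decP = params["dec"];
  Rcpp::List bottP = params["bott"], headP = params["head"];
  auto getw = [](const Rcpp::List& l, const char* nm) {
    Rcpp::List c = l[nm];
    return std::make_pair(conv_to<Mat<eT>>::from(Rcpp::as<mat>(c["w"])),
                          conv_to<Col<eT>>::from(Rcpp::as<vec>(c["b"])));
  };

  Cube<eT> cur = conv_to<Cube<eT>>::from(
    cube(const_cast<double*>(x.memptr()), x.n_rows, x.n_cols, 1, false));
  std::vector<BlockWST<eT>> enc(depth), dec(depth);
  BlockWST<eT> bott;
  std::vector<uvec> sw(depth);
  std::vector<Cube<eT>> up_in(depth);
  for (int i = 0; i < depth; ++i) {
    Rcpp::List li = encP[i];
    auto c1 = getw(li, "c1"), c2 = getw(li, "c2");
    blk_fwd(cur, c1.first, c1.second, c2.first, c2.second, k, enc[i]);
    Cube<eT> pooled;
    pool_fwd_t(enc[i].out, pooled, sw[i]);
    cur = pooled;
  }
  {
    auto c1 = getw(bottP, "c1"), c2 = getw(bottP, "c2");
    blk_fwd(cur, c1.first, c1.second, c2.first, c2.second, k, bott);
    cur = bott.out;
  }
  for (int i = depth - 1; i >= 0; --i) {
    Rcpp::List li = decP[i];
    auto up = getw(li, "up");
    up_in[i] = cur;
    Cube<eT> u = upconv_fwd_t(cur, up.first, up.second);
    Cube<eT> cat(u.n_rows, u.n_cols, u.n_slices + enc[i].out.n_slices);
    cat.slices(0, u.n_slices - 1) = u;
    cat.slices(u.n_slices, cat.n_slices - 1) = enc[i].out;
    auto c1 = getw(li, "c1"), c2 = getw(li, "c2");
    blk_fwd(cat, c1.first, c1.second, c2.first, c2.second, k, dec[i]);
    cur = dec[i].out;
  }
  Mat<eT> hw = conv_to<Mat<eT>>::from(Rcpp::as<mat>(headP["w"]));
  Col<eT> hb = conv_to<Col<eT>>::from(Rcpp::as<vec>(headP["b"]));
  const long long N = (long long)x.n_rows * x.n_cols;
  Mat<eT> F(const_cast<eT*>(cur.memptr()), N, cur.n_slices, false, true);
  Mat<eT> logits = F * hw;
  logits.each_row() += hb.t();
  // loss arithmetic in double for stable sums regardless of eT
  vec s = conv_to<vec>::from(logits.col(0) - logits.col(1));
  vec prob = 1.0 / (1.0 + exp(-s));
  vec t(N);
  const double* yp = y.memptr();
  for (long long q = 0; q < N; ++q) t[q] = yp[q] > 0 ? 1.0 : 0.0;

  double S = dot(prob, t), P = accu(prob), T = accu(t);
  double denom = P + T + 1.0;
  double dice_term = 1.0 - (2.0 * S + 1.0) / denom;
  vec pc = clamp(prob, 1e-7, 1.0 - 1e-7);
  double bce_term = -mean(t % log(pc) + (1.0 - t) % log(1.0 - pc));
  vec dprob = -(2.0 * t * denom - (2.0 * S + 1.0)) / (denom * denom);
  dprob += (-t / pc + (1.0 - t) / (1.0 - pc)) / (double)N;
  vec dsd = dprob % prob % (1.0 - prob);
  Col<eT> ds = conv_to<Col<eT>>::from(dsd);

  Mat<eT> dlog(N, 2);
  dlog.col(0) = ds; dlog.col(1) = -ds;
  Mat<eT> dhw = F.t() * dlog;
  Col<eT> dhb = sum(dlog, 0).t();
  Mat<eT> dF = dlog * hw.t();
  Cube<eT> dcur(dF.memptr(), cur.n_rows, cur.n_cols, cur.n_slices);

  Rcpp::List gEnc(depth), gDec(depth);
  std::vector<Cube<eT>> dskip(depth);
  for (int i = 0; i < depth; ++i) {
    Rcpp::List li = decP[i];
    auto c1 = getw(li, "c1"), c2 = getw(li, "c2");
    ConvGradT<eT> g1, g2, gu;
    Cube<eT> dcat = blk_bwd(dcur, dec[i], c1.first, c2.first, k, g1, g2);
    int co = dec[i].out.n_slices;
    Cube<eT> dup = dcat.slices(0, co - 1);
    dskip[i] = dcat.slices(co, dcat.n_slices - 1);
    auto up = getw(li, "up");
    dcur = upconv_bwd(up_in[i], up.first, dup, gu);
    gDec[i] = Rcpp::List::create(Rcpp::Named("up") = grad_pair(gu),
                                 Rcpp::Named("c1") = grad_pair(g1),
                                 Rcpp::Named("c2") = grad_pair(g2));
  }
  Rcpp::List gBott;
  {
    auto c1 = getw(bottP, "c1"), c2 = getw(bottP, "c2");
    ConvGradT<eT> g1, g2;
    dcur = blk_bwd(dcur, bott, c1.first, c2.first, k, g1, g2);
    gBott = Rcpp::List::create(Rcpp::Named("c1") = grad_pair(g1),
                               Rcpp::Named("c2") = grad_pair(g2));
  }
  for (int i = depth - 1; i >= 0; --i) {
    Rcpp::List li = encP[i];
    auto c1 = getw(li, "c1"), c2 = getw(li, "c2");
    Cube<eT> dpooled = pool_bwd(dcur, sw[i], enc[i].out.n_rows,
                                enc[i].out.n_cols);
    dpooled += dskip[i];
    ConvGradT<eT> g1, g2;
    dcur = blk_bwd(dpooled, enc[i], c1.first, c2.first, k, g1, g2);
    gEnc[i] = Rcpp::List::create(Rcpp::Named("c1") = grad_pair(g1),
                                 Rcpp::Named("c2") = grad_pair(g2));
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = dice_term + bce_term,
    Rcpp::Named("dice_term") = dice_term,
    Rcpp::Named("bce_term") = bce_term,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("enc") = gEnc, Rcpp::Named("bott") = gBott,
      Rcpp::Named("dec") = gDec,
      Rcpp::Named("head") = Rcpp::List::create(
        Rcpp::Named("w") = conv_to<mat>::from(dhw),
        Rcpp::Named("b") = conv_to<vec>::from(dhb))));
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_grad(const arma::mat& x, const arma::mat& y,
                         const Rcpp::List& params, int depth, int k,
                         bool single = false) {
  if (single) return unet_grad_impl<float>(x, y, params, depth, k);
  return unet_grad_impl<double>(x, y, params, depth, k);
}
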