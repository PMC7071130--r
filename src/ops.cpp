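// Hot numerical kernels for the network: 2-D convolution (stride 1, SAME
// zero padding) as im2col + BLAS gemm, 2x2/stride-1 valid max pooling,
// batch-norm scale/shift passes, and the GRU recurrence. Everything is
// deterministic; all RNG lives in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Transposed patch matrix Pt ((H*W) x (C*kh*kw)): column c*kh*kw + di*kw+dj
// holds input channel c shifted by the kernel offset (di, dj) under SAME
// zero padding, flattened column-major over output positions. Each column
// is filled with one contiguous submatrix copy. Single precision: the
// convolutions run in float32 (the gemms and patch shuffling dominate the
// training cost; ~1e-7 relative rounding is negligible against the
// optimizer noise), while parameters and every other layer stay double.
static fmat im2col_t(const fcube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  fmat Pt(H * W, C * kh * kw, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int col = c * kh * kw + di * kw + dj;
        const int i0 = std::max(0, ph - di), i1 = std::min(H - 1, H - 1 + ph - di);
        const int j0 = std::max(0, pw - dj), j1 = std::min(W - 1, W - 1 + pw - dj);
        if (i0 > i1 || j0 > j1) continue;
        fmat view(Pt.colptr(col), H, W, false, true);
        view.submat(i0, j0, i1, j1) =
            x.slice(c).submat(i0 + di - ph, j0 + dj - pw,
                              i1 + di - ph, j1 + dj - pw);
      }
    }
  }
  return Pt;
}

// Adjoint: scatter-add patch gradients back onto the input.
static void col2im_t(const fmat& dPt, fcube& dx, const int kh, const int kw) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int col = c * kh * kw + di * kw + dj;
        const int i0 = std::max(0, ph - di), i1 = std::min(H - 1, H - 1 + ph - di);
        const int j0 = std::max(0, pw - dj), j1 = std::min(W - 1, W - 1 + pw - dj);
        if (i0 > i1 || j0 > j1) continue;
        const fmat view(const_cast<float*>(dPt.colptr(col)), H, W, false, true);
        dx.slice(c).submat(i0 + di - ph, j0 + dj - pw,
                           i1 + di - ph, j1 + dj - pw) +=
            view.submat(i0, j0, i1, j1);
      }
    }
  }
}

// Forward convolution for several kernel-shape groups sharing one input.
// Ws[g]: n_k x (C*kh*kw); the result concatenates all groups' feature maps
// on the channel axis, pre-activation.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_forward(const arma::cube& x, const Rcpp::List& Ws,
                            const Rcpp::List& bs,
                            const arma::ivec& khs, const arma::ivec& kws,
                            const bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  const int G = Ws.size();
  const fcube xf = conv_to<fcube>::from(x);
  int total = 0;
  for (int g = 0; g < G; ++g) total += Rcpp::as<mat>(Ws[g]).n_rows;
  Rcpp::NumericVector out_r(Rcpp::no_init((R_xlen_t)H * W * total));
  out_r.attr("dim") = Rcpp::Dimension(H, W, total);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    const fmat Wg = conv_to<fmat>::from(Rcpp::as<mat>(Ws[g]));
    const fvec bg = conv_to<fvec>::from(Rcpp::as<vec>(bs[g]));
    const int kh = khs[g], kw = kws[g];
    if (kh > H)
      Rcpp::stop("kernel taller than the input (%d rows vs %d)", kh, H);
    if ((int)Wg.n_cols != (int)x.n_slices * kh * kw)
      Rcpp::stop("weight matrix does not match input channels x kernel size");
    const fmat Pt = im2col_t(xf, kh, kw);
    fmat Yt = Pt * Wg.t();                // (H*W) x n_k
    const int n_k = Wg.n_rows;
    for (int n = 0; n < n_k; ++n) Yt.col(n) += bg[n];
    double* op = out_r.begin() + (size_t)H * W * off;
    const float* yp = Yt.memptr();
    const size_t m = (size_t)H * W * n_k;
    if (relu) {
      for (size_t i = 0; i < m; ++i) op[i] = yp[i] > 0.0f ? yp[i] : 0.0;
    } else {
      for (size_t i = 0; i < m; ++i) op[i] = yp[i];
    }
    off += n_k;
  }
  return out_r;
}

// Backward convolution: dy holds the gradient on the concatenated
// pre-activation maps; returns dx plus per-group dW, db.
// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& x, const Rcpp::List& Ws,
                             const arma::cube& dy,
                             const arma::ivec& khs, const arma::ivec& kws) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int G = Ws.size();
  const fcube xf = conv_to<fcube>::from(x);
  fcube dxf(H, W, C, fill::zeros);
  Rcpp::List dWs(G), dbs(G);
  int off = 0;
  (void)0;
  for (int g = 0; g < G; ++g) {
    const fmat Wg = conv_to<fmat>::from(Rcpp::as<mat>(Ws[g]));
    const int kh = khs[g], kw = kws[g];
    const int n_k = Wg.n_rows;
    const fmat Pt = im2col_t(xf, kh, kw);
    fmat dYt(H * W, n_k);
    {
      const double* dp = dy.slice(off).memptr();
      float* fp = dYt.memptr();
      const size_t m = (size_t)H * W * n_k;
      for (size_t i = 0; i < m; ++i) fp[i] = (float)dp[i];
    }
    fmat dW = dYt.t() * Pt;               // n_k x (C*kh*kw)
    fvec db = sum(dYt, 0).t();
    fmat dPt = dYt * Wg;                  // (H*W) x (C*kh*kw)
    col2im_t(dPt, dxf, kh, kw);
    dWs[g] = conv_to<mat>::from(dW);
    dbs[g] = conv_to<vec>::from(db);
    off += n_k;
  }
  Rcpp::NumericVector dx_r(Rcpp::no_init((R_xlen_t)H * W * C));
  dx_r.attr("dim") = Rcpp::Dimension(H, W, C);
  {
    const float* fp = dxf.memptr();
    double* dp = dx_r.begin();
    const size_t m = dxf.n_elem;
    for (size_t i = 0; i < m; ++i) dp[i] = fp[i];
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_r,
                            Rcpp::Named("dWs") = dWs,
                            Rcpp::Named("dbs") = dbs);
}


// Double-precision instantiations of the same convolution (used for
// gradient verification and small exact tests; training uses the float
// path above).
static mat im2col_t_d(const cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat Pt(H * W, C * kh * kw, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int col = c * kh * kw + di * kw + dj;
        const int i0 = std::max(0, ph - di), i1 = std::min(H - 1, H - 1 + ph - di);
        const int j0 = std::max(0, pw - dj), j1 = std::min(W - 1, W - 1 + pw - dj);
        if (i0 > i1 || j0 > j1) continue;
        mat view(Pt.colptr(col), H, W, false, true);
        view.submat(i0, j0, i1, j1) =
            x.slice(c).submat(i0 + di - ph, j0 + dj - pw,
                              i1 + di - ph, j1 + dj - pw);
      }
    }
  }
  return Pt;
}

static void col2im_t_d(const mat& dPt, cube& dx, const int kh, const int kw) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const int col = c * kh * kw + di * kw + dj;
        const int i0 = std::max(0, ph - di), i1 = std::min(H - 1, H - 1 + ph - di);
        const int j0 = std::max(0, pw - dj), j1 = std::min(W - 1, W - 1 + pw - dj);
        if (i0 > i1 || j0 > j1) continue;
        const mat view(const_cast<double*>(dPt.colptr(col)), H, W, false, true);
        dx.slice(c).submat(i0 + di - ph, j0 + dj - pw,
                           i1 + di - ph, j1 + dj - pw) +=
            view.submat(i0, j0, i1, j1);
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_forward_dbl(const arma::cube& x, const Rcpp::List& Ws,
                                const Rcpp::List& bs,
                                const arma::ivec& khs, const arma::ivec& kws,
                                const bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  const int G = Ws.size();
  int total = 0;
  for (int g = 0; g < G; ++g) total += Rcpp::as<mat>(Ws[g]).n_rows;
  Rcpp::NumericVector out_r(Rcpp::no_init((R_xlen_t)H * W * total));
  out_r.attr("dim") = Rcpp::Dimension(H, W, total);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    const mat Wg = Rcpp::as<mat>(Ws[g]);
    const vec bg = Rcpp::as<vec>(bs[g]);
    const int kh = khs[g], kw = kws[g];
    if (kh > H)
      Rcpp::stop("kernel taller than the input (%d rows vs %d)", kh, H);
    if ((int)Wg.n_cols != (int)x.n_slices * kh * kw)
      Rcpp::stop("weight matrix does not match input channels x kernel size");
    const mat Pt = im2col_t_d(x, kh, kw);
    mat Yt = Pt * Wg.t();
    const int n_k = Wg.n_rows;
    for (int n = 0; n < n_k; ++n) Yt.col(n) += bg[n];
    if (relu) Yt.transform([](double v) { return v > 0.0 ? v : 0.0; });
    std::memcpy(out_r.begin() + (size_t)H * W * off, Yt.memptr(),
                sizeof(double) * H * W * n_k);
    off += n_k;
  }
  return out_r;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward_dbl(const arma::cube& x, const Rcpp::List& Ws,
                                 const arma::cube& dy,
                                 const arma::ivec& khs, const arma::ivec& kws) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int G = Ws.size();
  cube dx(H, W, C, fill::zeros);
  Rcpp::List dWs(G), dbs(G);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    const mat Wg = Rcpp::as<mat>(Ws[g]);
    const int kh = khs[g], kw = kws[g];
    const int n_k = Wg.n_rows;
    const mat Pt = im2col_t_d(x, kh, kw);
    const mat dYt(const_cast<double*>(dy.slice(off).memptr()),
                  H * W, n_k, false, true);
    mat dW = dYt.t() * Pt;
    vec db = sum(dYt, 0).t();
    mat dPt = dYt * Wg;
    col2im_t_d(dPt, dx, kh, kw);
    dWs[g] = dW;
    dbs[g] = db;
    off += n_k;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dWs") = dWs,
                            Rcpp::Named("dbs") = dbs);
}

// dy gated by the ReLU mask (y > 0), in one pass.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_relu_gate(const Rcpp::NumericVector& dy,
                                  const Rcpp::NumericVector& y) {
  Rcpp::NumericVector out(Rcpp::no_init(dy.size()));
  out.attr("dim") = dy.attr("dim");
  const double* yp = y.begin();
  const double* dp = dy.begin();
  double* op = out.begin();
  const size_t m = dy.size();
  for (size_t i = 0; i < m; ++i) op[i] = yp[i] > 0.0 ? dp[i] : 0.0;
  return out;
}

// One-pass per-column mean and mean of squares.
// [[Rcpp::export]]
Rcpp::List cpp_colstats(const arma::mat& M) {
  const uword n = M.n_rows, C = M.n_cols;
  vec mu(C), msq(C);
  for (uword c = 0; c < C; ++c) {
    const double* p = M.colptr(c);
    double s = 0, s2 = 0;
    for (uword i = 0; i < n; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    mu[c] = s / n;
    msq[c] = s2 / n;
  }
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("meansq") = msq);
}

// 2x2 max pooling with stride 1 (valid): output is one smaller per spatial
// dimension. The argmax code (0..3: di + 2*dj) is kept for the backward
// pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H < 2 || W < 2) Rcpp::stop("map smaller than the 2x2 pooling window");
  Rcpp::NumericVector y_r(Rcpp::no_init((R_xlen_t)(H - 1) * (W - 1) * C));
  y_r.attr("dim") = Rcpp::Dimension(H - 1, W - 1, C);
  Rcpp::IntegerVector arg(Rcpp::no_init((R_xlen_t)(H - 1) * (W - 1) * C));
  int* argp = arg.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice(c).memptr();
    double* yc = y_r.begin() + (size_t)(H - 1) * (W - 1) * c;
    for (int j = 0; j < W - 1; ++j) {
      const double* col0 = xc + j * H;
      const double* col1 = xc + (j + 1) * H;
      for (int i = 0; i < H - 1; ++i) {
        double best = col0[i];
        int code = 0;
        if (col0[i + 1] > best) { best = col0[i + 1]; code = 1; }
        if (col1[i] > best) { best = col1[i]; code = 2; }
        if (col1[i + 1] > best) { best = col1[i + 1]; code = 3; }
        yc[j * (H - 1) + i] = best;
        *argp++ = code;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y_r, Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool_backward(const arma::cube& dy,
                                const Rcpp::IntegerVector& arg,
                                const int H, const int W) {
  const int C = dy.n_slices, h = dy.n_rows, w = dy.n_cols;
  Rcpp::NumericVector dx((R_xlen_t)H * W * C);   // zero-initialized
  dx.attr("dim") = Rcpp::Dimension(H, W, C);
  const int* argp = arg.begin();
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + (size_t)H * W * c;
    const double* dyc = dy.slice(c).memptr();
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const int code = *argp++;
        dxc[(j + (code >> 1)) * H + i + (code & 1)] += dyc[j * h + i];
      }
    }
  }
  return dx;
}

// Batch-norm helpers: column-recycled affine passes over big
// (observations x features) matrices, done in one sweep-free pass.

// y = M * a[col] + b[col] (column-contiguous passes)
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_colscale_shift(const arma::mat& M, const arma::vec& a,
                             const arma::vec& b) {
  Rcpp::NumericMatrix y_r(Rcpp::no_init(M.n_rows, M.n_cols));
  mat y(y_r.begin(), M.n_rows, M.n_cols, false, true);
  for (uword c = 0; c < M.n_cols; ++c) y.col(c) = M.col(c) * a[c] + b[c];
  return y_r;
}

// Fused batch-norm apply: xhat = M*a + b, y = xhat*gamma + beta, both in
// one pass over M.
// [[Rcpp::export]]
Rcpp::List cpp_bn_apply(const arma::mat& M, const arma::vec& a,
                        const arma::vec& b, const arma::vec& gamma,
                        const arma::vec& beta) {
  Rcpp::NumericMatrix xhat_r(Rcpp::no_init(M.n_rows, M.n_cols));
  Rcpp::NumericMatrix y_r(Rcpp::no_init(M.n_rows, M.n_cols));
  mat xhat(xhat_r.begin(), M.n_rows, M.n_cols, false, true);
  mat y(y_r.begin(), M.n_rows, M.n_cols, false, true);
  for (uword c = 0; c < M.n_cols; ++c) {
    xhat.col(c) = M.col(c) * a[c] + b[c];
    y.col(c) = xhat.col(c) * gamma[c] + beta[c];
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat_r,
                            Rcpp::Named("y") = y_r);
}

// colSums(A % B) without materializing the product
// [[Rcpp::export]]
arma::vec cpp_colsums_prod(const arma::mat& A, const arma::mat& B) {
  return sum(A % B, 0).t();
}

// dx = (dy - c1[col] - xhat * c2[col]) * c3[col]
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_bn_backward_dx(const arma::mat& dy, const arma::mat& xhat,
                             const arma::vec& c1, const arma::vec& c2,
                             const arma::vec& c3) {
  Rcpp::NumericMatrix dx_r(Rcpp::no_init(dy.n_rows, dy.n_cols));
  mat dx(dx_r.begin(), dy.n_rows, dy.n_cols, false, true);
  for (uword c = 0; c < dy.n_cols; ++c)
    dx.col(c) = (dy.col(c) - c1[c] - xhat.col(c) * c2[c]) * c3[c];
  return dx_r;
}

static inline vec sigmoid(const vec& v) { return 1.0 / (1.0 + exp(-v)); }

// GRU forward over a whole sequence. X: input_dim x T, columns are time
// steps. Gates:
//   z_t = sigmoid(Wxz x_t + Whz h_{t-1} + bz)
//   r_t = sigmoid(Wxr x_t + Whr h_{t-1} + br)
//   hc_t = tanh(Wxh x_t + W (r_t . h_{t-1}) [+ bh])
//   h_t = (1 - z_t) . h_{t-1} + z_t . hc_t
// The candidate line carries no bias unless `bh` is non-empty.
// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(const arma::mat& X,
                           const arma::mat& Wxz, const arma::mat& Whz,
                           const arma::mat& Wxr, const arma::mat& Whr,
                           const arma::mat& Wxh, const arma::mat& W,
                           const arma::vec& bz, const arma::vec& br,
                           const arma::vec& bh) {
  const int T = X.n_cols, h = Wxz.n_rows;
  if ((int)Wxz.n_cols != (int)X.n_rows)
    Rcpp::stop("input width %d does not match Wxz (%d columns)",
               (int)X.n_rows, (int)Wxz.n_cols);
  const bool use_bh = bh.n_elem > 0;
  mat H(h, T), Z(h, T), R(h, T), Hc(h, T);
  vec h_prev(h, fill::zeros);
  const mat Az = Wxz * X, Ar = Wxr * X, Ah = Wxh * X;   // input projections
  for (int t = 0; t < T; ++t) {
    vec z = sigmoid(Az.col(t) + Whz * h_prev + bz);
    vec r = sigmoid(Ar.col(t) + Whr * h_prev + br);
    vec pre = Ah.col(t) + W * (r % h_prev);
    if (use_bh) pre += bh;
    vec hc = tanh(pre);
    vec ht = (1.0 - z) % h_prev + z % hc;
    Z.col(t) = z; R.col(t) = r; Hc.col(t) = hc; H.col(t) = ht;
    h_prev = ht;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("Hc") = Hc);
}

// GRU backward through time. dH holds the loss gradient w.r.t. every
// hidden state. Returns parameter gradients and dX.
// [[Rcpp::export]]
Rcpp::List cpp_gru_backward(const arma::mat& X,
                            const arma::mat& Wxz, const arma::mat& Whz,
                            const arma::mat& Wxr, const arma::mat& Whr,
                            const arma::mat& Wxh, const arma::mat& W,
                            const arma::mat& H, const arma::mat& Z,
                            const arma::mat& R, const arma::mat& Hc,
                            const arma::mat& dH, const bool use_bh) {
  const int T = X.n_cols, h = Wxz.n_rows, k = X.n_rows;
  mat dWxz(h, k, fill::zeros), dWhz(h, h, fill::zeros);
  mat dWxr(h, k, fill::zeros), dWhr(h, h, fill::zeros);
  mat dWxh(h, k, fill::zeros), dW(h, h, fill::zeros);
  vec dbz(h, fill::zeros), dbr(h, fill::zeros), dbh(h, fill::zeros);
  mat dX(k, T, fill::zeros);
  vec carry(h, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const vec h_prev = (t > 0) ? vec(H.col(t - 1)) : vec(h, fill::zeros);
    const vec z = Z.col(t), r = R.col(t), hc = Hc.col(t);
    const vec dh = dH.col(t) + carry;
    const vec dz = dh % (hc - h_prev);
    const vec dhc = dh % z;
    vec dh_prev = dh % (1.0 - z);
    const vec dhc_pre = dhc % (1.0 - hc % hc);
    dWxh += dhc_pre * X.col(t).t();
    dW += dhc_pre * (r % h_prev).t();
    if (use_bh) dbh += dhc_pre;
    const vec drh = W.t() * dhc_pre;      // gradient w.r.t. r . h_prev
    const vec dr = drh % h_prev;
    dh_prev += drh % r;
    const vec dz_pre = dz % z % (1.0 - z);
    const vec dr_pre = dr % r % (1.0 - r);
    dWxz += dz_pre * X.col(t).t();
    dWhz += dz_pre * h_prev.t();
    dbz += dz_pre;
    dWxr += dr_pre * X.col(t).t();
    dWhr += dr_pre * h_prev.t();
    dbr += dr_pre;
    dh_prev += Whz.t() * dz_pre + Whr.t() * dr_pre;
    dX.col(t) = Wxz.t() * dz_pre + Wxr.t() * dr_pre + Wxh.t() * dhc_pre;
    carry = dh_prev;
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWxz") = dWxz,
      Rcpp::Named("dWhz") = dWhz, Rcpp::Named("dWxr") = dWxr,
      Rcpp::Named("dWhr") = dWhr, Rcpp::Named("dWxh") = dWxh,
      Rcpp::Named("dW") = dW, Rcpp::Named("dbz") = dbz,
      Rcpp::Named("dbr") = dbr, Rcpp::Named("dbh") = dbh);
}
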