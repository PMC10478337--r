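// Compact single-precision convolutional-network engine for the dual-branch
// trainer: a U-Net style encoder-decoder built from 3x3 'same' convolutions
// (im2col + GEMM), ReLU, 2x2 max-pooling, nearest-neighbour upsampling with a
// 1x1 channel-reduction convolution, skip concatenation, and a sigmoid 1x1
// output head. Forward caches every intermediate needed for the exact
// backward pass inside a persistent context object that is reused across
// training steps (buffer sizes are constant, so reuse avoids large
// allocation churn).
//
// Activations are stored as (H*W) x C matrices, pixel index p = i + H*j
// (column-major, matching R arrays). Weights arrive from R as double arrays
// dim c(k,k,Cin,Cout) whose column-major layout maps directly onto the
// (k*k*Cin) x Cout GEMM matrix used here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct ConvW {
  fmat W;        // (k*k*Cin) x Cout
  frowvec b;     // 1 x Cout
  frowvec gamma; // instance-norm scale (empty for the head)
  frowvec beta;  // instance-norm shift
  int k;         // kernel side (1 or 3)
  bool has_norm;
};

// im2col for 3x3 'same' convolution with zero padding, into a reusable buffer.
// A: (H*W) x C -> cols: (H*W) x (9*C), column q = (a+1) + 3*(b+1) + 9*c for
// offset (a, b) in {-1,0,1}^2 applied to the SOURCE pixel.
static void im2col3(const fmat& A, int H, int W, fmat& cols) {
  const int C = A.n_cols;
  cols.zeros(H * (size_t)W, 9 * (size_t)C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (int b = -1; b <= 1; ++b) {
      for (int a = -1; a <= 1; ++a) {
        const int q = (a + 1) + 3 * (b + 1) + 9 * c;
        float* dst = cols.colptr(q);
        const int i0 = std::max(0, -a), i1 = H - 1 - std::max(0, a);
        const int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int j = 0; j < W; ++j) {
          const int js = j + b;
          if (js < 0 || js >= W) continue;
          std::memcpy(dst + i0 + (size_t)H * j,
                      src + (i0 + a) + (size_t)H * js,
                      sizeof(float) * len);
        }
      }
    }
  }
}

// transpose of im2col3: scatter-add dCols back onto the input grid.
static fmat col2im3(const fmat& dCols, int H, int W, int C) {
  fmat dA(H * (size_t)W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    for (int b = -1; b <= 1; ++b) {
      for (int a = -1; a <= 1; ++a) {
        const int q = (a + 1) + 3 * (b + 1) + 9 * c;
        const float* src = dCols.colptr(q);
        const int i0 = std::max(0, -a), i1 = H - 1 - std::max(0, a);
        if (i1 < i0) continue;
        for (int j = 0; j < W; ++j) {
          const int js = j + b;
          if (js < 0 || js >= W) continue;
          float* d = dst + (i0 + a) + (size_t)H * js;
          const float* s = src + i0 + (size_t)H * j;
          for (int i = 0; i <= i1 - i0; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dA;
}

struct ConvCache { fmat cols; fmat xhat; frowvec sinv; int H, W, Cin; };

// affine instance norm: per-channel standardization over the image plane
static const float kNormEps = 1e-5f;

static void inorm_fwd(fmat& Y, const ConvW& cw, ConvCache& cc) {
  const uword n = Y.n_rows;
  cc.xhat.set_size(Y.n_rows, Y.n_cols);
  cc.sinv.set_size(Y.n_cols);
  for (uword c = 0; c < Y.n_cols; ++c) {
    float* y = Y.colptr(c);
    float mu = 0.f; for (uword i = 0; i < n; ++i) mu += y[i];
    mu /= n;
    float v = 0.f; for (uword i = 0; i < n; ++i) { float d = y[i]-mu; v += d*d; }
    v /= n;
    const float sinv = 1.0f / std::sqrt(v + kNormEps);
    cc.sinv[c] = sinv;
    float* xh = cc.xhat.colptr(c);
    const float g = cw.gamma[c], b = cw.beta[c];
    for (uword i = 0; i < n; ++i) {
      xh[i] = (y[i] - mu) * sinv;
      y[i] = g * xh[i] + b;
    }
  }
}

static void inorm_bwd(fmat& dY, const ConvW& cw, const ConvCache& cc,
                      frowvec& dgamma, frowvec& dbeta) {
  const uword n = dY.n_rows;
  for (uword c = 0; c < dY.n_cols; ++c) {
    float* dy = dY.colptr(c);
    const float* xh = cc.xhat.colptr(c);
    float sg = 0.f, sb = 0.f;
    for (uword i = 0; i < n; ++i) { sg += dy[i]*xh[i]; sb += dy[i]; }
    dgamma[c] += sg; dbeta[c] += sb;
    const float g = cw.gamma[c], sinv = cc.sinv[c];
    const float m_dxh = sb * g / n, m_dxh_xh = sg * g / n;
    for (uword i = 0; i < n; ++i)
      dy[i] = sinv * (dy[i]*g - m_dxh - xh[i]*m_dxh_xh);
  }
}

static fmat conv_fwd(const fmat& A, const ConvW& cw, int H, int W, ConvCache& cc) {
  cc.H = H; cc.W = W; cc.Cin = A.n_cols;
  fmat Y;
  if (cw.k == 1) {
    cc.cols = A; // reuses buffer when size matches
    Y = A * cw.W;
  } else {
    im2col3(A, H, W, cc.cols);
    Y = cc.cols * cw.W;
  }
  Y.each_row() += cw.b;
  if (cw.has_norm) inorm_fwd(Y, cw, cc);
  return Y;
}

static fmat conv_bwd(fmat dY, const ConvW& cw, const ConvCache& cc,
                     fmat& dW, frowvec& db, frowvec& dgamma, frowvec& dbeta) {
  if (cw.has_norm) inorm_bwd(dY, cw, cc, dgamma, dbeta);
  dW += cc.cols.t() * dY;
  db += sum(dY, 0);
  fmat dCols = dY * cw.W.t();
  if (cw.k == 1) return dCols;
  return col2im3(dCols, cc.H, cc.W, cc.Cin);
}

// leaky ReLU (slope 0.01): keeps a small gradient on inactive units so the
// compact backbone cannot collapse into an all-dead state
static const float kLeak = 0.01f;

static void relu_inplace(fmat& A) {
  float* p = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i) if (p[i] < 0.f) p[i] *= kLeak;
}

// scale dA by the activation derivative (1 on active, kLeak on inactive)
static void relu_mask_inplace(fmat& dA, const fmat& act) {
  float* p = dA.memptr();
  const float* a = act.memptr();
  for (uword i = 0; i < dA.n_elem; ++i) if (a[i] <= 0.f) p[i] *= kLeak;
}

// 2x2 max pool; argmax stored as flat pixel index into the input grid.
static fmat pool_fwd(const fmat& A, int H, int W, umat& amax) {
  const int Ho = H / 2, Wo = W / 2, C = A.n_cols;
  fmat Y(Ho * (size_t)Wo, C);
  amax.set_size(Ho * (size_t)Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = Y.colptr(c);
    uword* am = amax.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int p00 = 2*i   + H*(2*j), p10 = 2*i+1 + H*(2*j);
        const int p01 = 2*i   + H*(2*j+1), p11 = 2*i+1 + H*(2*j+1);
        int best = p00; float v = src[p00];
        if (src[p10] > v) { v = src[p10]; best = p10; }
        if (src[p01] > v) { v = src[p01]; best = p01; }
        if (src[p11] > v) { v = src[p11]; best = p11; }
        dst[i + (size_t)Ho*j] = v;
        am[i + (size_t)Ho*j] = best;
      }
    }
  }
  return Y;
}

static fmat pool_bwd(const fmat& dY, const umat& amax, int H, int W) {
  const int C = dY.n_cols;
  fmat dA(H * (size_t)W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    const float* src = dY.colptr(c);
    const uword* am = amax.colptr(c);
    for (uword p = 0; p < dY.n_rows; ++p) dst[am[p]] += src[p];
  }
  return dA;
}

// nearest-neighbour 2x upsample
static fmat up_fwd(const fmat& A, int h, int w) {
  const int C = A.n_cols, H = 2*h, W = 2*w;
  fmat Y(H * (size_t)W, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = Y.colptr(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dst[i + (size_t)H*j] = src[(i/2) + (size_t)h*(j/2)];
  }
  return Y;
}

static fmat up_bwd(const fmat& dY, int h, int w) {
  const int C = dY.n_cols, H = 2*h, W = 2*w;
  fmat dA(h * (size_t)w, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    const float* src = dY.colptr(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dst[(i/2) + (size_t)h*(j/2)] += src[i + (size_t)H*j];
  }
  return dA;
}

// ---- network description -------------------------------------------------
// Per level: `nconv` 3x3 conv+ReLU then pool; bottleneck: `nconv` convs;
// decoder level: nearest upsample, 1x1 reduce conv+ReLU, concat skip,
// `nconv` 3x3 conv+ReLU; head: 1x1 conv + sigmoid.

struct NetDef { int side, depth, width, nconv; };

static int n_convs(const NetDef& d) {
  return d.nconv * d.depth + d.nconv + d.depth * (1 + d.nconv) + 1;
}

struct ImgCache {
  std::vector<ConvCache> cc;
  std::vector<fmat> relu_out;   // post-ReLU output per conv (empty for head)
  std::vector<umat> pool_amax;
  std::vector<fmat> skip;
  fvec prob;
  bool full = false;            // cache valid for backward
};

struct UNetCache {
  NetDef def;
  std::vector<ConvW> cw;
  std::vector<ImgCache> img;
};

static void load_weights(Rcpp::List weights, const NetDef& d, std::vector<ConvW>& cw) {
  const int nc = n_convs(d);
  if ((int)weights.size() != 4 * (nc - 1) + 2)
    Rcpp::stop("weight list has wrong length (%d, expected %d)",
               (int)weights.size(), 4 * (nc - 1) + 2);
  cw.resize(nc);
  int wi = 0;
  for (int l = 0; l < nc; ++l) {
    ConvW& c = cw[l];
    c.has_norm = (l != nc - 1);
    Rcpp::NumericVector Wv = weights[wi++];
    Rcpp::NumericVector bv = weights[wi++];
    Rcpp::IntegerVector dim = Wv.attr("dim");
    c.k = dim[0];
    const int rows = dim[0]*dim[1]*dim[2], cols = dim[3];
    c.W.set_size(rows, cols);
    for (int i = 0; i < rows*cols; ++i) c.W[i] = (float)Wv[i];
    c.b.set_size(cols);
    for (int i = 0; i < cols; ++i) c.b[i] = (float)bv[i];
    if (c.has_norm) {
      Rcpp::NumericVector gv = weights[wi++];
      Rcpp::NumericVector bev = weights[wi++];
      c.gamma.set_size(cols); c.beta.set_size(cols);
      for (int i = 0; i < cols; ++i) c.gamma[i] = (float)gv[i];
      for (int i = 0; i < cols; ++i) c.beta[i] = (float)bev[i];
    }
  }
}

static void forward_img(const NetDef& d, const std::vector<ConvW>& cw,
                        const fvec& x, ImgCache& ic, bool keep) {
  const int nc = n_convs(d);
  ic.cc.resize(nc); ic.relu_out.resize(nc);
  ic.pool_amax.resize(d.depth); ic.skip.resize(d.depth);
  int li = 0;
  int H = d.side, W = d.side;
  fmat A(x);
  for (int l = 0; l < d.depth; ++l) {
    for (int r = 0; r < d.nconv; ++r) {
      A = conv_fwd(A, cw[li], H, W, ic.cc[li]);
      relu_inplace(A);
      if (keep) ic.relu_out[li] = A;
      ++li;
    }
    ic.skip[l] = A;
    A = pool_fwd(A, H, W, ic.pool_amax[l]);
    H /= 2; W /= 2;
  }
  for (int r = 0; r < d.nconv; ++r) {
    A = conv_fwd(A, cw[li], H, W, ic.cc[li]);
    relu_inplace(A);
    if (keep) ic.relu_out[li] = A;
    ++li;
  }
  for (int l = d.depth - 1; l >= 0; --l) {
    A = up_fwd(A, H, W); H *= 2; W *= 2;
    A = conv_fwd(A, cw[li], H, W, ic.cc[li]);  // 1x1 reduce
    relu_inplace(A);
    if (keep) ic.relu_out[li] = A;
    ++li;
    A = join_rows(ic.skip[l], A);
    for (int r = 0; r < d.nconv; ++r) {
      A = conv_fwd(A, cw[li], H, W, ic.cc[li]);
      relu_inplace(A);
      if (keep) ic.relu_out[li] = A;
      ++li;
    }
  }
  A = conv_fwd(A, cw[li], H, W, ic.cc[li]); ++li;
  ic.prob = 1.0f / (1.0f + exp(-A.col(0)));
  ic.full = keep;
}

static void backward_img(const NetDef& d, const std::vector<ConvW>& cw,
                         const ImgCache& ic, const fvec& dLdz,
                         std::vector<fmat>& dW, std::vector<frowvec>& db,
                         std::vector<frowvec>& dgamma,
                         std::vector<frowvec>& dbeta) {
  int li = n_convs(d) - 1;
  fmat dA = conv_bwd(fmat(dLdz), cw[li], ic.cc[li], dW[li], db[li], dgamma[li], dbeta[li]); --li;
  int H = d.side, W = d.side;
  std::vector<fmat> dskip(d.depth);
  // decoder levels in reverse emission order: level 0 (full res) first
  for (int l = 0; l < d.depth; ++l) {
    for (int r = 0; r < d.nconv; ++r) {
      relu_mask_inplace(dA, ic.relu_out[li]);
      dA = conv_bwd(dA, cw[li], ic.cc[li], dW[li], db[li], dgamma[li], dbeta[li]); --li;
    }
    const int cs = ic.skip[l].n_cols;
    dskip[l] = dA.cols(0, cs - 1);
    fmat dUp = dA.cols(cs, dA.n_cols - 1);
    relu_mask_inplace(dUp, ic.relu_out[li]);
    dUp = conv_bwd(dUp, cw[li], ic.cc[li], dW[li], db[li], dgamma[li], dbeta[li]); --li;  // 1x1 reduce
    dA = up_bwd(dUp, H/2, W/2);
    H /= 2; W /= 2;
  }
  for (int r = 0; r < d.nconv; ++r) {
    relu_mask_inplace(dA, ic.relu_out[li]);
    dA = conv_bwd(dA, cw[li], ic.cc[li], dW[li], db[li], dgamma[li], dbeta[li]); --li;
  }
  for (int l = d.depth - 1; l >= 0; --l) {
    dA = pool_bwd(dA, ic.pool_amax[l], H*2, W*2);
    H *= 2; W *= 2;
    dA += dskip[l];
    for (int r = 0; r < d.nconv; ++r) {
      relu_mask_inplace(dA, ic.relu_out[li]);
      dA = conv_bwd(dA, cw[li], ic.cc[li], dW[li], db[li], dgamma[li], dbeta[li]); --li;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".unet_ctx_new")]]
SEXP unet_ctx_new() {
  Rcpp::XPtr<UNetCache> ptr(new UNetCache(), true);
  return ptr;
}

// [[Rcpp::export(name = ".unet_forward_cpp")]]
Rcpp::NumericVector unet_forward_cpp(SEXP ctx, Rcpp::List weights,
                                     Rcpp::NumericVector x,
                                     int side, int depth, int width, int nconv,
                                     bool keep_cache) {
  Rcpp::XPtr<UNetCache> uc(ctx);
  NetDef d; d.side = side; d.depth = depth; d.width = width; d.nconv = nconv;
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != side || dim[1] != side)
    Rcpp::stop("input batch must be side x side x n");
  const int B = dim[2];
  const size_t npix = (size_t)side * side;

  uc->def = d;
  load_weights(weights, d, uc->cw);
  if ((int)uc->img.size() < B) uc->img.resize(B);

  Rcpp::NumericVector out(x.size());
  out.attr("dim") = dim;
  fvec xi(npix);
  for (int bimg = 0; bimg < B; ++bimg) {
    for (size_t p = 0; p < npix; ++p) xi[p] = (float)x[bimg*npix + p];
    forward_img(d, uc->cw, xi, uc->img[bimg], keep_cache);
    const fvec& pr = uc->img[bimg].prob;
    for (size_t p = 0; p < npix; ++p) out[bimg*npix + p] = (double)pr[p];
  }
  return out;
}

// [[Rcpp::export(name = ".unet_backward_cpp")]]
Rcpp::List unet_backward_cpp(SEXP ctx, Rcpp::NumericVector dLdz) {
  Rcpp::XPtr<UNetCache> uc(ctx);
  const NetDef& d = uc->def;
  const int nc = n_convs(d);
  const size_t npix = (size_t)d.side * d.side;
  Rcpp::IntegerVector dim = dLdz.attr("dim");
  if (dim.size() != 3 || (size_t)dim[0]*dim[1] != npix)
    Rcpp::stop("gradient batch shape mismatch");
  const int B = dim[2];
  if (B > (int)uc->img.size())
    Rcpp::stop("gradient batch larger than cached forward batch");

  std::vector<fmat> dW(nc);
  std::vector<frowvec> db(nc), dgamma(nc), dbeta(nc);
  for (int l = 0; l < nc; ++l) {
    dW[l].zeros(uc->cw[l].W.n_rows, uc->cw[l].W.n_cols);
    db[l].zeros(uc->cw[l].b.n_elem);
    dgamma[l].zeros(uc->cw[l].b.n_elem);
    dbeta[l].zeros(uc->cw[l].b.n_elem);
  }
  fvec g(npix);
  for (int bimg = 0; bimg < B; ++bimg) {
    if (!uc->img[bimg].full)
      Rcpp::stop("forward pass was run without keep_cache");
    for (size_t p = 0; p < npix; ++p) g[p] = (float)dLdz[bimg*npix + p];
    backward_img(d, uc->cw, uc->img[bimg], g, dW, db, dgamma, dbeta);
  }
  Rcpp::List out(4 * (nc - 1) + 2);
  int wi = 0;
  for (int l = 0; l < nc; ++l) {
    Rcpp::NumericVector Wv(dW[l].n_elem);
    for (uword i = 0; i < dW[l].n_elem; ++i) Wv[i] = (double)dW[l][i];
    Rcpp::NumericVector bv(db[l].n_elem);
    for (uword i = 0; i < db[l].n_elem; ++i) bv[i] = (double)db[l][i];
    out[wi++] = Wv; out[wi++] = bv;
    if (uc->cw[l].has_norm) {
      Rcpp::NumericVector gv(dgamma[l].n_elem), bev(dbeta[l].n_elem);
      for (uword i = 0; i < dgamma[l].n_elem; ++i) gv[i] = (double)dgamma[l][i];
      for (uword i = 0; i < dbeta[l].n_elem; ++i) bev[i] = (double)dbeta[l][i];
      out[wi++] = gv; out[wi++] = bev;
    }
  }
  return out;
}
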