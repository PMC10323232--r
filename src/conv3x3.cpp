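// 3x3 same-padding convolution, forward and backward, on activation arrays
// laid out (H, W, N, C) in R's column-major order. Weights are a
// (9*Cin) x Cout matrix with rows indexed offset-major, offset o = dx*3 + dy
// for dx, dy in {0,1,2}, the (dy, dx) offset reading input pixel
// (h + dy - 1, w + dx - 1). Implemented as per-image im2col + BLAS GEMM.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather the 3x3 patches of one (H x W x Cin) image into (H*W) x (9*Cin)
static void im2col_image(const double* img, int H, int W, int Cin,
                         arma::mat& cols) {
  cols.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* plane = img + static_cast<size_t>(ci) * H * W;
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        const int o = dx * 3 + dy;
        double* dst = cols.colptr(o * Cin + ci);
        const int oy = dy - 1, ox = dx - 1;
        const int h0 = std::max(0, -oy), h1 = std::min(H, H - oy);
        for (int w = std::max(0, -ox); w < std::min(W, W - ox); ++w) {
          const double* src = plane + static_cast<size_t>(w + ox) * H + oy;
          double* d = dst + static_cast<size_t>(w) * H;
          for (int h = h0; h < h1; ++h) d[h] = src[h];
        }
      }
    }
  }
}

// note: the (H, W, N, C) layout means image n's channel ci starts at
// offset (ci*N + n) * H*W; channels of one image are strided by N planes
static void gather_image(const double* a, int H, int W, int N, int Cin,
                         int n, arma::mat& buf) {
  const size_t plane = static_cast<size_t>(H) * W;
  for (int ci = 0; ci < Cin; ++ci)
    std::copy(a + (static_cast<size_t>(ci) * N + n) * plane,
              a + (static_cast<size_t>(ci) * N + n + 1) * plane,
              buf.memptr() + static_cast<size_t>(ci) * plane);
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_fw(const NumericVector& A, const IntegerVector& dimA,
                             const NumericMatrix& Wm) {
  const int H = dimA[0], W = dimA[1], N = dimA[2], Cin = dimA[3];
  const int Cout = Wm.ncol();
  const size_t plane = static_cast<size_t>(H) * W;
  NumericVector Y(static_cast<R_xlen_t>(plane) * N * Cout);
  arma::mat Wa(const_cast<double*>(Wm.begin()), 9 * Cin, Cout, false, true);
  arma::mat cols(plane, 9 * Cin);
  arma::mat img(plane, Cin);
  arma::mat out(plane, Cout);
  for (int n = 0; n < N; ++n) {
    gather_image(A.begin(), H, W, N, Cin, n, img);
    im2col_image(img.memptr(), H, W, Cin, cols);
    out = cols * Wa;
    for (int co = 0; co < Cout; ++co)
      std::copy(out.colptr(co), out.colptr(co) + plane,
                Y.begin() + (static_cast<size_t>(co) * N + n) * plane);
  }
  Y.attr("dim") = IntegerVector::create(H, W, N, Cout);
  return Y;
}

// scatter-add a (H*W) x (9*Cin) gradient matrix back onto image gradients
static void col2im_image(const arma::mat& dcols, int H, int W, int Cin,
                         double* dimg) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* plane = dimg + static_cast<size_t>(ci) * H * W;
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        const int o = dx * 3 + dy;
        const double* src = dcols.colptr(o * Cin + ci);
        const int oy = dy - 1, ox = dx - 1;
        const int h0 = std::max(0, -oy), h1 = std::min(H, H - oy);
        for (int w = std::max(0, -ox); w < std::min(W, W - ox); ++w) {
          double* d = plane + static_cast<size_t>(w + ox) * H + oy;
          const double* s = src + static_cast<size_t>(w) * H;
          for (int h = h0; h < h1; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv3x3_bw(const NumericVector& A, const IntegerVector& dimA,
                    const NumericVector& dY, const NumericMatrix& Wm,
                    const bool need_dx) {
  const int H = dimA[0], W = dimA[1], N = dimA[2], Cin = dimA[3];
  const int Cout = Wm.ncol();
  const size_t plane = static_cast<size_t>(H) * W;
  arma::mat Wa(const_cast<double*>(Wm.begin()), 9 * Cin, Cout, false, true);
  arma::mat dW(9 * Cin, Cout, arma::fill::zeros);
  NumericVector dX;
  if (need_dx) dX = NumericVector(static_cast<R_xlen_t>(plane) * N * Cin);
  arma::mat cols(plane, 9 * Cin);
  arma::mat img(plane, Cin);
  arma::mat g(plane, Cout);
  arma::mat dimg(plane, Cin);
  for (int n = 0; n < N; ++n) {
    gather_image(A.begin(), H, W, N, Cin, n, img);
    im2col_image(img.memptr(), H, W, Cin, cols);
    for (int co = 0; co < Cout; ++co)
      std::copy(dY.begin() + (static_cast<size_t>(co) * N + n) * plane,
                dY.begin() + (static_cast<size_t>(co) * N + n + 1) * plane,
                g.colptr(co));
    dW += cols.t() * g;
    if (need_dx) {
      arma::mat dcols = g * Wa.t();
      dimg.zeros();
      col2im_image(dcols, H, W, Cin, dimg.memptr());
      for (int ci = 0; ci < Cin; ++ci)
        std::copy(dimg.colptr(ci), dimg.colptr(ci) + plane,
                  dX.begin() + (static_cast<size_t>(ci) * N + n) * plane);
    }
  }
  List out = List::create(Named("dW") = wrap(dW));
  if (need_dx) {
    dX.attr("dim") = IntegerVector::create(H, W, N, Cin);
    out["dX"] = dX;
  } else {
    out["dX"] = R_NilValue;
  }
  return out;
}

// ---- batch normalisation ---------------------------------------------------
// M is the activation flattened to (n x C); training mode returns the
// normalised activations plus the statistics needed for the backward pass

// [[Rcpp::export]]
List cpp_bn_fw_train(const NumericVector& M, const int n, const int C,
                     const NumericVector& gamma, const NumericVector& beta,
                     const double eps, const bool relu) {
  NumericVector Y(static_cast<R_xlen_t>(n) * C);
  NumericVector xhat(static_cast<R_xlen_t>(n) * C);
  LogicalVector mask;
  if (relu) mask = LogicalVector(static_cast<R_xlen_t>(n) * C);
  NumericVector mu(C), va(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* m = M.begin() + static_cast<R_xlen_t>(c) * n;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += m[i]; s2 += m[i] * m[i]; }
    const double mean = s / n;
    double var = s2 / n - mean * mean;
    if (var < 0) var = 0;
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = mean; va[c] = var; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* xh = xhat.begin() + static_cast<R_xlen_t>(c) * n;
    double* y = Y.begin() + static_cast<R_xlen_t>(c) * n;
    if (relu) {
      int* mk = LOGICAL(mask) + static_cast<R_xlen_t>(c) * n;
      for (int i = 0; i < n; ++i) {
        xh[i] = (m[i] - mean) * is;
        const double yv = xh[i] * g + b;
        mk[i] = yv > 0;
        y[i] = yv > 0 ? yv : 0.0;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        xh[i] = (m[i] - mean) * is;
        y[i] = xh[i] * g + b;
      }
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = xhat,
                      Named("mu") = mu, Named("var") = va,
                      Named("invstd") = invstd, Named("mask") = mask);
}

// [[Rcpp::export]]
NumericVector cpp_bn_fw_infer(const NumericVector& M, const int n, const int C,
                              const NumericVector& scale,
                              const NumericVector& shift, const bool relu) {
  NumericVector Y(static_cast<R_xlen_t>(n) * C);
  for (int c = 0; c < C; ++c) {
    const double* m = M.begin() + static_cast<R_xlen_t>(c) * n;
    double* y = Y.begin() + static_cast<R_xlen_t>(c) * n;
    const double sc = scale[c], sh = shift[c];
    if (relu) {
      for (int i = 0; i < n; ++i) {
        const double yv = m[i] * sc + sh;
        y[i] = yv > 0 ? yv : 0.0;
      }
    } else {
      for (int i = 0; i < n; ++i) y[i] = m[i] * sc + sh;
    }
  }
  return Y;
}

// dM is the gradient arriving at the (optional) fused ReLU output; mask
// (from the forward pass) gates it before the batch-norm backward proper
// [[Rcpp::export]]
List cpp_bn_bw(const NumericVector& dM_in, const NumericVector& xhat,
               const int n, const int C, const NumericVector& gamma,
               const NumericVector& invstd, const Nullable<LogicalVector> mask_) {
  NumericVector dM;
  if (mask_.isNotNull()) {
    LogicalVector mask(mask_);
    dM = NumericVector(static_cast<R_xlen_t>(n) * C);
    const int* mk = LOGICAL(mask);
    const double* src = dM_in.begin();
    double* dst = dM.begin();
    const R_xlen_t len = static_cast<R_xlen_t>(n) * C;
    for (R_xlen_t i = 0; i < len; ++i) dst[i] = mk[i] ? src[i] : 0.0;
  } else {
    dM = dM_in;
  }
  NumericVector dX(static_cast<R_xlen_t>(n) * C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* g = dM.begin() + static_cast<R_xlen_t>(c) * n;
    const double* xh = xhat.begin() + static_cast<R_xlen_t>(c) * n;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += g[i] * xh[i]; sb += g[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double ga = gamma[c];
    const double m_dxhat = ga * sb / n;        // mean of dxhat
    const double m_dxhat_x = ga * sg / n;      // mean of dxhat * xhat
    const double is = invstd[c];
    double* dx = dX.begin() + static_cast<R_xlen_t>(c) * n;
    for (int i = 0; i < n; ++i)
      dx[i] = (ga * g[i] - m_dxhat - xh[i] * m_dxhat_x) * is;
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// ---- 2x2 max pooling -------------------------------------------------------
// argmax stored as 0..3 meaning (dy, dx) = (0,0), (1,0), (0,1), (1,1)

// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericVector& A, const IntegerVector& dimA,
                    const bool need_argmax) {
  const int H = dimA[0], W = dimA[1], N = dimA[2], C = dimA[3];
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t nout = static_cast<R_xlen_t>(Ho) * Wo * N * C;
  NumericVector Y(nout);
  IntegerVector am;
  if (need_argmax) am = IntegerVector(nout);
  const double* a = A.begin();
  const size_t planeA = static_cast<size_t>(H) * W;
  const size_t planeY = static_cast<size_t>(Ho) * Wo;
  for (R_xlen_t nc = 0; nc < static_cast<R_xlen_t>(N) * C; ++nc) {
    const double* ap = a + nc * planeA;
    double* yp = Y.begin() + nc * planeY;
    int* amp = need_argmax ? am.begin() + nc * planeY : nullptr;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = ap + static_cast<size_t>(2 * wo) * H;
      const double* c1 = c0 + H;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho;
        double best = c0[h]; int arg = 0;
        if (c0[h + 1] > best) { best = c0[h + 1]; arg = 1; }
        if (c1[h] > best) { best = c1[h]; arg = 2; }
        if (c1[h + 1] > best) { best = c1[h + 1]; arg = 3; }
        yp[static_cast<size_t>(wo) * Ho + ho] = best;
        if (need_argmax) amp[static_cast<size_t>(wo) * Ho + ho] = arg;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(Named("Y") = Y,
                      Named("argmax") = need_argmax ? am : IntegerVector(0));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& dY, const IntegerVector& am,
                             const IntegerVector& dimA) {
  const int H = dimA[0], W = dimA[1], N = dimA[2], C = dimA[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dX(static_cast<R_xlen_t>(H) * W * N * C);
  const size_t planeA = static_cast<size_t>(H) * W;
  const size_t planeY = static_cast<size_t>(Ho) * Wo;
  for (R_xlen_t nc = 0; nc < static_cast<R_xlen_t>(N) * C; ++nc) {
    const double* gp = dY.begin() + nc * planeY;
    const int* amp = am.begin() + nc * planeY;
    double* dp = dX.begin() + nc * planeA;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t io = static_cast<size_t>(wo) * Ho + ho;
        const int arg = amp[io];
        const int h = 2 * ho + (arg & 1);
        const int w = 2 * wo + (arg >> 1);
        dp[static_cast<size_t>(w) * H + h] = gp[io];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  return dX;
}

// ---- 3D connected components (26-connectivity) -----------------------------
// union-find over the voxel grid; mask is a logical array (t, y, x) in
// column-major order. Returns integer labels (0 = background), components
// numbered in first-voxel order.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d_26(const LogicalVector& mask,
                             const IntegerVector& dims) {
  const int nt = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nt) * ny * nx;
  std::vector<int> parent(n);
  const int* m = LOGICAL(mask);
  // offsets to "previous" neighbours (lexicographically smaller indices)
  std::vector<R_xlen_t> offs;
  std::vector<std::array<int, 3>> doffs;
  for (int dx = -1; dx <= 0; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dt = -1; dt <= 1; ++dt) {
        if (dx > 0) continue;
        if (dx == 0 && (dy > 0 || (dy == 0 && dt >= 0))) continue;
        offs.push_back(static_cast<R_xlen_t>(dx) * nt * ny +
                       static_cast<R_xlen_t>(dy) * nt + dt);
        doffs.push_back({dt, dy, dx});
      }
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = i;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (static_cast<R_xlen_t>(x) * ny + y) * nt;
      for (int t = 0; t < nt; ++t) {
        const R_xlen_t i = base + t;
        if (!m[i]) continue;
        for (size_t k = 0; k < offs.size(); ++k) {
          const int tt = t + doffs[k][0], yy = y + doffs[k][1],
                    xx = x + doffs[k][2];
          if (tt < 0 || tt >= nt || yy < 0 || yy >= ny || xx < 0) continue;
          const R_xlen_t j = i + offs[k];
          if (!m[j]) continue;
          const int ri = uf_find(parent, i), rj = uf_find(parent, j);
          if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
        }
      }
    }
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i]) { lab[i] = 0; continue; }
    const int r = uf_find(parent, i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  lab.attr("dim") = dims;
  return lab;
}


// ---- global max pool over the (h, w) grid ---------------------------------
// A is (h, w, N, C); returns (N x C) features and flat argmax indices

// [[Rcpp::export]]
List cpp_gpool_fw(const NumericVector& A, const IntegerVector& dimA,
                  const bool need_argmax) {
  const int h = dimA[0], w = dimA[1], N = dimA[2], C = dimA[3];
  const int hw = h * w;
  NumericMatrix F(N, C);
  IntegerVector am;
  if (need_argmax) am = IntegerVector(static_cast<R_xlen_t>(N) * C);
  const double* a = A.begin();
  for (R_xlen_t nc = 0; nc < static_cast<R_xlen_t>(N) * C; ++nc) {
    const double* p = a + nc * hw;
    int best = 0;
    for (int i = 1; i < hw; ++i) if (p[i] > p[best]) best = i;
    F[nc] = p[best];
    if (need_argmax) am[nc] = best;
  }
  return List::create(Named("F") = F,
                      Named("argmax") = need_argmax ? am : IntegerVector(0));
}

// [[Rcpp::export]]
NumericVector cpp_gpool_bw(const NumericMatrix& dF, const IntegerVector& am,
                           const IntegerVector& dimA) {
  const int h = dimA[0], w = dimA[1], N = dimA[2], C = dimA[3];
  const int hw = h * w;
  NumericVector dX(static_cast<R_xlen_t>(hw) * N * C);
  for (R_xlen_t nc = 0; nc < static_cast<R_xlen_t>(N) * C; ++nc)
    dX[nc * hw + am[nc]] = dF[nc];
  dX.attr("dim") = dimA;
  return dX;
}
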