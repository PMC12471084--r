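// Dense 3D kernels for the registration network.
//
// All feature arrays are column-major with dim (C, D, H, W): channel fastest,
// then depth, height, width.  Deformation/velocity fields are (3, D, H, W)
// with component order (d, h, w).  Heavy convolutions go through a chunked
// im2col and single-precision GEMM; everything else is direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline size_t vidx(int c, int d, int h, int w, int C, int D, int H) {
  return (size_t)c + (size_t)C * ((size_t)d + (size_t)D * ((size_t)h + (size_t)H * (size_t)w));
}

// ---------------------------------------------------------------- conv3d ---
//
// Same-padding stride-1 3D convolution computed as one small GEMM per kernel
// offset on a zero-padded copy of the input: with channel-fastest layout a
// uniform spatial shift is a uniform column shift of the (C x Vp) matrix, so
// each offset contributes  Y[:, v] += W_o * Xp[:, v + delta]  over one
// contiguous column range.  No im2col buffer, float GEMM throughout.

static std::vector<float> to_float(const NumericVector& x) {
  std::vector<float> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

// copy (C,D,H,W) into zero-padded (C,D+2p,H+2p,W+2p)
static std::vector<float> pad_vol(const double* x, int C, int D, int H, int W, int p) {
  const int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<float> xp((size_t)C * Dp * Hp * Wp, 0.0f);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double* src = x + vidx(0, 0, h, w, C, D, H);
      float* dst = xp.data() + vidx(0, p, h + p, w + p, C, Dp, Hp);
      for (int d = 0; d < D; ++d)
        for (int c = 0; c < C; ++c) *dst++ = (float)*src++;
    }
  return xp;
}

// weights w: dim (Cout, Cin, k, k, k); bias length Cout
// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, int cout, int k,
                            NumericVector bias) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = (k - 1) / 2;
  const int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t Vp = (size_t)Dp * Hp * Wp;
  const size_t P = (size_t)p * (1 + (size_t)Dp * (1 + (size_t)Hp)); // first true voxel
  const size_t n = Vp - 2 * P;                                      // gemm width
  std::vector<float> xp = pad_vol(x.begin(), C, D, H, W, p);
  std::vector<float> wf = to_float(w);
  std::vector<float> yp((size_t)cout * Vp, 0.0f);
  arma::fmat Yv(yp.data() + (size_t)cout * P, cout, n, false, true);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        const long delta = (kd - p) + (long)Dp * ((kh - p) + (long)Hp * (kw - p));
        arma::fmat Wo(wf.data() + (size_t)cout * C * (kd + k * (kh + k * kw)),
                      cout, C, false, true);
        arma::fmat Xv(xp.data() + (size_t)C * (P + delta), C, n, false, true);
        Yv += Wo * Xv;
      }
  NumericVector out((R_xlen_t)cout * D * H * W);
  for (int w2 = 0; w2 < W; ++w2)
    for (int h = 0; h < H; ++h) {
      const float* src = yp.data() + vidx(0, p, h + p, w2 + p, cout, Dp, Hp);
      double* dst = out.begin() + vidx(0, 0, h, w2, cout, D, H);
      for (int d = 0; d < D; ++d)
        for (int c = 0; c < cout; ++c) *dst++ = (double)*src++ + bias[c];
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector gout, NumericVector x, IntegerVector xdim,
                   NumericVector w, int cout, int k, bool need_gx) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = (k - 1) / 2;
  const int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t Vp = (size_t)Dp * Hp * Wp;
  const size_t P = (size_t)p * (1 + (size_t)Dp * (1 + (size_t)Hp));
  const size_t n = Vp - 2 * P;
  std::vector<float> xp = pad_vol(x.begin(), C, D, H, W, p);
  std::vector<float> gyp = pad_vol(gout.begin(), cout, D, H, W, p);
  std::vector<float> wf = to_float(w);
  arma::fmat gYv(gyp.data() + (size_t)cout * P, cout, n, false, true);
  NumericVector gwv((R_xlen_t)cout * C * k * k * k);
  NumericVector gb(cout);
  std::vector<float> gxp;
  if (need_gx) gxp.assign((size_t)C * Vp, 0.0f);
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        const long delta = (kd - p) + (long)Dp * ((kh - p) + (long)Hp * (kw - p));
        // weight gradient: gW_o = gY[:, v] * Xp[:, v+delta]^T  (padded border
        // columns of gY are zero and contribute nothing)
        arma::fmat Xv(xp.data() + (size_t)C * (P + delta), C, n, false, true);
        arma::fmat gWo = gYv * Xv.t();
        std::copy(gWo.memptr(), gWo.memptr() + (size_t)cout * C,
                  gwv.begin() + (size_t)cout * C * (kd + k * (kh + k * kw)));
        if (need_gx) {
          arma::fmat Wo(wf.data() + (size_t)cout * C * (kd + k * (kh + k * kw)),
                        cout, C, false, true);
          arma::fmat gXv(gxp.data() + (size_t)C * (P + delta), C, n, false, true);
          gXv += Wo.t() * gYv;
        }
      }
  for (size_t j = 0; j < (size_t)D * H * W; ++j)
    for (int c = 0; c < cout; ++c) gb[c] += gout[j * cout + c];
  NumericVector gxv;
  if (need_gx) {
    gxv = NumericVector((R_xlen_t)C * D * H * W);
    for (int w2 = 0; w2 < W; ++w2)
      for (int h = 0; h < H; ++h) {
        const float* src = gxp.data() + vidx(0, p, h + p, w2 + p, C, Dp, Hp);
        double* dst = gxv.begin() + vidx(0, 0, h, w2, C, D, H);
        for (int d = 0; d < D; ++d)
          for (int c = 0; c < C; ++c) *dst++ = (double)*src++;
      }
  }
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gb);
}

// ------------------------------------------------------------- max pool ---

// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector xdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)C * Do * Ho * Wo);
  IntegerVector amax(out.size());
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t bidx = 0;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                size_t ii = vidx(c, 2 * d + od, 2 * h + oh, 2 * w + ow, C, D, H);
                if (x[ii] > best) { best = x[ii]; bidx = ii; }
              }
          size_t oi = vidx(c, d, h, w, C, Do, Ho);
          out[oi] = best;
          amax[oi] = (int)bidx;
        }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(NumericVector gout, IntegerVector amax, int n_in) {
  NumericVector gx(n_in);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[amax[i]] += gout[i];
  return gx;
}

// ------------------------------------------------------------- resample ---

// Generic trilinear / nearest resampling between grids, preserving physical
// extent (output voxel i samples input at (i + 0.5) * S/T - 0.5, clamped).
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector xdim,
                             IntegerVector odim, bool nearest) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  NumericVector out((R_xlen_t)C * Do * Ho * Wo);
  for (int w = 0; w < Wo; ++w) {
    double pw = std::min(std::max((w + 0.5) * sw - 0.5, 0.0), (double)(W - 1));
    for (int h = 0; h < Ho; ++h) {
      double ph = std::min(std::max((h + 0.5) * sh - 0.5, 0.0), (double)(H - 1));
      for (int d = 0; d < Do; ++d) {
        double pd = std::min(std::max((d + 0.5) * sd - 0.5, 0.0), (double)(D - 1));
        if (nearest) {
          int id = (int)std::lround(pd), ih = (int)std::lround(ph), iw = (int)std::lround(pw);
          for (int c = 0; c < C; ++c)
            out[vidx(c, d, h, w, C, Do, Ho)] = x[vidx(c, id, ih, iw, C, D, H)];
        } else {
          int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph), w0 = (int)std::floor(pw);
          int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
          double fd = pd - d0, fh = ph - h0, fw = pw - w0;
          for (int c = 0; c < C; ++c) {
            double v =
              (1 - fd) * (1 - fh) * (1 - fw) * x[vidx(c, d0, h0, w0, C, D, H)] +
              fd * (1 - fh) * (1 - fw) * x[vidx(c, d1, h0, w0, C, D, H)] +
              (1 - fd) * fh * (1 - fw) * x[vidx(c, d0, h1, w0, C, D, H)] +
              fd * fh * (1 - fw) * x[vidx(c, d1, h1, w0, C, D, H)] +
              (1 - fd) * (1 - fh) * fw * x[vidx(c, d0, h0, w1, C, D, H)] +
              fd * (1 - fh) * fw * x[vidx(c, d1, h0, w1, C, D, H)] +
              (1 - fd) * fh * fw * x[vidx(c, d0, h1, w1, C, D, H)] +
              fd * fh * fw * x[vidx(c, d1, h1, w1, C, D, H)];
            out[vidx(c, d, h, w, C, Do, Ho)] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of trilinear cpp_resample3d (used for the x2 decoder upsampling).
// [[Rcpp::export]]
NumericVector cpp_resample3d_bw(NumericVector gout, IntegerVector xdim,
                                IntegerVector odim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  NumericVector gx((R_xlen_t)C * D * H * W);
  for (int w = 0; w < Wo; ++w) {
    double pw = std::min(std::max((w + 0.5) * sw - 0.5, 0.0), (double)(W - 1));
    for (int h = 0; h < Ho; ++h) {
      double ph = std::min(std::max((h + 0.5) * sh - 0.5, 0.0), (double)(H - 1));
      for (int d = 0; d < Do; ++d) {
        double pd = std::min(std::max((d + 0.5) * sd - 0.5, 0.0), (double)(D - 1));
        int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph), w0 = (int)std::floor(pw);
        int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
        double fd = pd - d0, fh = ph - h0, fw = pw - w0;
        for (int c = 0; c < C; ++c) {
          double g = gout[vidx(c, d, h, w, C, Do, Ho)];
          gx[vidx(c, d0, h0, w0, C, D, H)] += (1 - fd) * (1 - fh) * (1 - fw) * g;
          gx[vidx(c, d1, h0, w0, C, D, H)] += fd * (1 - fh) * (1 - fw) * g;
          gx[vidx(c, d0, h1, w0, C, D, H)] += (1 - fd) * fh * (1 - fw) * g;
          gx[vidx(c, d1, h1, w0, C, D, H)] += fd * fh * (1 - fw) * g;
          gx[vidx(c, d0, h0, w1, C, D, H)] += (1 - fd) * (1 - fh) * fw * g;
          gx[vidx(c, d1, h0, w1, C, D, H)] += fd * (1 - fh) * fw * g;
          gx[vidx(c, d0, h1, w1, C, D, H)] += (1 - fd) * fh * fw * g;
          gx[vidx(c, d1, h1, w1, C, D, H)] += fd * fh * fw * g;
        }
      }
    }
  }
  return gx;
}

// ---------------------------------------------------- spatial transformer ---

// warp: out(p) = img(p + phi(p)); sample positions clamp to the border.
// img (C,D,H,W); phi (3,D,H,W) in voxel units, component order (d,h,w).
// [[Rcpp::export]]
NumericVector cpp_grid_sample_fw(NumericVector img, IntegerVector idim,
                                 NumericVector phi, bool nearest) {
  const int C = idim[0], D = idim[1], H = idim[2], W = idim[3];
  NumericVector out(img.size());
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t pv = 3 * ((size_t)d + (size_t)D * (h + (size_t)H * w));
        double pd = std::min(std::max(d + phi[pv], 0.0), (double)(D - 1));
        double ph = std::min(std::max(h + phi[pv + 1], 0.0), (double)(H - 1));
        double pw = std::min(std::max(w + phi[pv + 2], 0.0), (double)(W - 1));
        if (nearest) {
          int id = (int)std::lround(pd), ih = (int)std::lround(ph), iw = (int)std::lround(pw);
          for (int c = 0; c < C; ++c)
            out[vidx(c, d, h, w, C, D, H)] = img[vidx(c, id, ih, iw, C, D, H)];
        } else {
          int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph), w0 = (int)std::floor(pw);
          int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
          double fd = pd - d0, fh = ph - h0, fw = pw - w0;
          for (int c = 0; c < C; ++c) {
            double v =
              (1 - fd) * ((1 - fh) * ((1 - fw) * img[vidx(c, d0, h0, w0, C, D, H)] +
                                      fw * img[vidx(c, d0, h0, w1, C, D, H)]) +
                          fh * ((1 - fw) * img[vidx(c, d0, h1, w0, C, D, H)] +
                                fw * img[vidx(c, d0, h1, w1, C, D, H)])) +
              fd * ((1 - fh) * ((1 - fw) * img[vidx(c, d1, h0, w0, C, D, H)] +
                                fw * img[vidx(c, d1, h0, w1, C, D, H)]) +
                    fh * ((1 - fw) * img[vidx(c, d1, h1, w0, C, D, H)] +
                          fw * img[vidx(c, d1, h1, w1, C, D, H)]));
            out[vidx(c, d, h, w, C, D, H)] = v;
          }
        }
      }
  return out;
}

// Gradients of the trilinear warp w.r.t. the image and the field.
// [[Rcpp::export]]
List cpp_grid_sample_bw(NumericVector gout, NumericVector img,
                        IntegerVector idim, NumericVector phi) {
  const int C = idim[0], D = idim[1], H = idim[2], W = idim[3];
  NumericVector gimg(img.size());
  NumericVector gphi(phi.size());
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t pv = 3 * ((size_t)d + (size_t)D * (h + (size_t)H * w));
        double rd = d + phi[pv], rh = h + phi[pv + 1], rw = w + phi[pv + 2];
        bool ind = rd > 0.0 && rd < D - 1.0;
        bool inh = rh > 0.0 && rh < H - 1.0;
        bool inw = rw > 0.0 && rw < W - 1.0;
        double pd = std::min(std::max(rd, 0.0), (double)(D - 1));
        double ph = std::min(std::max(rh, 0.0), (double)(H - 1));
        double pw = std::min(std::max(rw, 0.0), (double)(W - 1));
        int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph), w0 = (int)std::floor(pw);
        int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
        double fd = pd - d0, fh = ph - h0, fw = pw - w0;
        double gd = 0, gh = 0, gw_ = 0;
        for (int c = 0; c < C; ++c) {
          double g = gout[vidx(c, d, h, w, C, D, H)];
          if (g == 0.0) continue;
          double v000 = img[vidx(c, d0, h0, w0, C, D, H)], v100 = img[vidx(c, d1, h0, w0, C, D, H)];
          double v010 = img[vidx(c, d0, h1, w0, C, D, H)], v110 = img[vidx(c, d1, h1, w0, C, D, H)];
          double v001 = img[vidx(c, d0, h0, w1, C, D, H)], v101 = img[vidx(c, d1, h0, w1, C, D, H)];
          double v011 = img[vidx(c, d0, h1, w1, C, D, H)], v111 = img[vidx(c, d1, h1, w1, C, D, H)];
          gimg[vidx(c, d0, h0, w0, C, D, H)] += (1 - fd) * (1 - fh) * (1 - fw) * g;
          gimg[vidx(c, d1, h0, w0, C, D, H)] += fd * (1 - fh) * (1 - fw) * g;
          gimg[vidx(c, d0, h1, w0, C, D, H)] += (1 - fd) * fh * (1 - fw) * g;
          gimg[vidx(c, d1, h1, w0, C, D, H)] += fd * fh * (1 - fw) * g;
          gimg[vidx(c, d0, h0, w1, C, D, H)] += (1 - fd) * (1 - fh) * fw * g;
          gimg[vidx(c, d1, h0, w1, C, D, H)] += fd * (1 - fh) * fw * g;
          gimg[vidx(c, d0, h1, w1, C, D, H)] += (1 - fd) * fh * fw * g;
          gimg[vidx(c, d1, h1, w1, C, D, H)] += fd * fh * fw * g;
          gd += g * ((1 - fh) * (1 - fw) * (v100 - v000) + fh * (1 - fw) * (v110 - v010) +
                     (1 - fh) * fw * (v101 - v001) + fh * fw * (v111 - v011));
          gh += g * ((1 - fd) * (1 - fw) * (v010 - v000) + fd * (1 - fw) * (v110 - v100) +
                     (1 - fd) * fw * (v011 - v001) + fd * fw * (v111 - v101));
          gw_ += g * ((1 - fd) * (1 - fh) * (v001 - v000) + fd * (1 - fh) * (v101 - v100) +
                      (1 - fd) * fh * (v011 - v010) + fd * fh * (v111 - v110));
        }
        if (ind) gphi[pv] = gd;
        if (inh) gphi[pv + 1] = gh;
        if (inw) gphi[pv + 2] = gw_;
      }
  return List::create(_["gimg"] = gimg, _["gphi"] = gphi);
}

// ------------------------------------------------------------------ adam ---

// In-place Adam update; theta, m and v are owned exclusively by the trainer.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector theta, NumericVector g, NumericVector m,
                   NumericVector v, int t, double lr, double b1, double b2,
                   double eps) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  const R_xlen_t n = theta.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    theta[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// ------------------------------------------------------- gaussian smooth ---

// Separable Gaussian smoothing of a (D,H,W) scalar field, replicate padding.
// [[Rcpp::export]]
NumericVector cpp_smooth_gauss3(NumericVector x, IntegerVector dims, double sigma) {
  const int D = dims[0], H = dims[1], W = dims[2];
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += ker[i + r]; }
  for (auto& v : ker) v /= s;
  std::vector<double> a(x.begin(), x.end()), b(x.size());
  const int dim3[3] = {D, H, W};
  const size_t stride[3] = {1, (size_t)D, (size_t)D * H};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dim3[ax];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          const int idx3[3] = {d, h, w};
          size_t base = (size_t)d + (size_t)D * (h + (size_t)H * w);
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int j = std::min(std::max(idx3[ax] + i, 0), n - 1);
            size_t off = base + ((size_t)j - idx3[ax]) * stride[ax];
            acc += ker[i + r] * a[off];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(x.size());
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}
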