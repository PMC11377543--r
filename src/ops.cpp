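// Low-level numeric kernels: plain and deformable convolution (forward and
// backward), bilinear resizing, affine warping, CRC32.  All image arrays are
// R arrays in H x W x C layout (column-major: element (h,w,c) lives at
// h + H*(w + W*c)); convolution weights are kh x kw x Cin x Cout.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double at3(const double *a, int H, int W, int h, int w, int c) {
  return a[h + (size_t)H * (w + (size_t)W * c)];
}
static inline double &ref3(double *a, int H, int W, int h, int w, int c) {
  return a[h + (size_t)H * (w + (size_t)W * c)];
}

// Zero-padded read: out-of-frame samples read zero.
static inline double read0(const double *a, int H, int W, int h, int w, int c) {
  if (h < 0 || h >= H || w < 0 || w >= W) return 0.0;
  return at3(a, H, W, h, w, c);
}

// Bilinear sample with zero fill outside the frame.
static double bilin0(const double *a, int H, int W, int c, double r, double q) {
  int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
  double fr = r - r0, fq = q - q0;
  double v00 = read0(a, H, W, r0, q0, c);
  double v01 = read0(a, H, W, r0, q0 + 1, c);
  double v10 = read0(a, H, W, r0 + 1, q0, c);
  double v11 = read0(a, H, W, r0 + 1, q0 + 1, c);
  return (1 - fr) * ((1 - fq) * v00 + fq * v01) + fr * ((1 - fq) * v10 + fq * v11);
}

// Partial derivatives of the bilinear sample w.r.t. the sampling coordinates.
static void bilin0_grad_coord(const double *a, int H, int W, int c, double r,
                              double q, double &dr, double &dq) {
  int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
  double fr = r - r0, fq = q - q0;
  double v00 = read0(a, H, W, r0, q0, c);
  double v01 = read0(a, H, W, r0, q0 + 1, c);
  double v10 = read0(a, H, W, r0 + 1, q0, c);
  double v11 = read0(a, H, W, r0 + 1, q0 + 1, c);
  dr = (1 - fq) * (v10 - v00) + fq * (v11 - v01);
  dq = (1 - fr) * (v01 - v00) + fr * (v11 - v10);
}

// Scatter the adjoint of a bilinear read back onto the input grid.
static void bilin0_scatter(double *ga, int H, int W, int c, double r, double q,
                           double g) {
  int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
  double fr = r - r0, fq = q - q0;
  if (r0 >= 0 && r0 < H && q0 >= 0 && q0 < W) ref3(ga, H, W, r0, q0, c) += (1 - fr) * (1 - fq) * g;
  if (r0 >= 0 && r0 < H && q0 + 1 >= 0 && q0 + 1 < W) ref3(ga, H, W, r0, q0 + 1, c) += (1 - fr) * fq * g;
  if (r0 + 1 >= 0 && r0 + 1 < H && q0 >= 0 && q0 < W) ref3(ga, H, W, r0 + 1, q0, c) += fr * (1 - fq) * g;
  if (r0 + 1 >= 0 && r0 + 1 < H && q0 + 1 >= 0 && q0 + 1 < W) ref3(ga, H, W, r0 + 1, q0 + 1, c) += fr * fq * g;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector A, NumericVector W,
                                 NumericVector bias, int stride, int pad) {
  IntegerVector da = A.attr("dim"), dw = W.attr("dim");
  int H = da[0], Wd = da[1], Ci = da[2];
  int kh = dw[0], kw = dw[1], Co = dw[3];
  if (dw[2] != Ci) stop("channel mismatch in conv2d");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (Wd + 2 * pad - kw) / stride + 1;
  NumericVector out(Ho * Wo * Co);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co);
  const double *a = A.begin(), *w = W.begin();
  double *o = out.begin();
  size_t kstep = (size_t)kh * kw * Ci;
  // co-contiguous copy of the kernel for cache-friendly accumulation
  std::vector<double> kp((size_t)Co * kstep);
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      kp[(size_t)co + (size_t)Co * t] = w[t + kstep * co];
  std::vector<double> acc(Co);
  for (int y = 0; y < Wo; ++y)
    for (int x = 0; x < Ho; ++x) {
      for (int co = 0; co < Co; ++co) acc[co] = bias[co];
      for (int ci = 0; ci < Ci; ++ci)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            int r = x * stride - pad + i, q = y * stride - pad + j;
            if (r < 0 || r >= H || q < 0 || q >= Wd) continue;
            double aval = at3(a, H, Wd, r, q, ci);
            if (aval == 0.0) continue;
            const double *krow = kp.data() +
                (size_t)Co * (i + (size_t)kh * (j + (size_t)kw * ci));
            for (int co = 0; co < Co; ++co) acc[co] += krow[co] * aval;
          }
      for (int co = 0; co < Co; ++co) ref3(o, Ho, Wo, x, y, co) = acc[co];
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector A, NumericVector W, NumericVector gOut,
                         int stride, int pad) {
  IntegerVector da = A.attr("dim"), dw = W.attr("dim"), dg = gOut.attr("dim");
  int H = da[0], Wd = da[1], Ci = da[2];
  int kh = dw[0], kw = dw[1], Co = dw[3];
  int Ho = dg[0], Wo = dg[1];
  NumericVector gA(A.size()), gW(W.size()), gb(Co);
  gA.attr("dim") = da;
  gW.attr("dim") = dw;
  const double *a = A.begin(), *w = W.begin(), *g = gOut.begin();
  double *pa = gA.begin(), *pw = gW.begin();
  size_t kstep = (size_t)kh * kw * Ci;
  std::vector<double> kp((size_t)Co * kstep), gwp((size_t)Co * kstep, 0.0);
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      kp[(size_t)co + (size_t)Co * t] = w[t + kstep * co];
  std::vector<double> gv(Co);
  for (int y = 0; y < Wo; ++y)
    for (int x = 0; x < Ho; ++x) {
      for (int co = 0; co < Co; ++co) {
        gv[co] = at3(g, Ho, Wo, x, y, co);
        gb[co] += gv[co];
      }
      for (int ci = 0; ci < Ci; ++ci)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            int r = x * stride - pad + i, q = y * stride - pad + j;
            if (r < 0 || r >= H || q < 0 || q >= Wd) continue;
            double aval = at3(a, H, Wd, r, q, ci);
            size_t t = i + (size_t)kh * (j + (size_t)kw * ci);
            const double *krow = kp.data() + (size_t)Co * t;
            double *gwrow = gwp.data() + (size_t)Co * t;
            double wsum = 0.0;
            for (int co = 0; co < Co; ++co) {
              gwrow[co] += gv[co] * aval;
              wsum += gv[co] * krow[co];
            }
            ref3(pa, H, Wd, r, q, ci) += wsum;
          }
    }
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      pw[t + kstep * co] = gwp[(size_t)co + (size_t)Co * t];
  return List::create(_["input"] = gA, _["weight"] = gW, _["bias"] = gb);
}

// Deformable convolution, stride 1, output size equal to input size.
// base_grid mode samples at (x + i - cr + u_i, y + j - cc + v_j); literal
// mode samples at (x + u_i, y + v_j) exactly as the printed sum.
// [[Rcpp::export]]
NumericVector cpp_deform_forward(NumericVector A, NumericVector K,
                                 NumericVector u, NumericVector v,
                                 bool base_grid) {
  IntegerVector da = A.attr("dim"), dk = K.attr("dim");
  int H = da[0], Wd = da[1], Ci = da[2];
  int kh = dk[0], kw = dk[1], Co = dk[3];
  if (dk[2] != Ci) stop("channel mismatch in deformable convolution");
  double cr = (kh - 1) / 2.0, cc = (kw - 1) / 2.0;
  NumericVector out(H * Wd * Co);
  out.attr("dim") = IntegerVector::create(H, Wd, Co);
  const double *a = A.begin(), *k = K.begin();
  double *o = out.begin();
  size_t kstep = (size_t)kh * kw * Ci;
  std::vector<double> kp((size_t)Co * kstep);
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      kp[(size_t)co + (size_t)Co * t] = k[t + kstep * co];
  std::vector<double> acc(Co);
  for (int y = 0; y < Wd; ++y)
    for (int x = 0; x < H; ++x) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double r = base_grid ? x + (i - cr) + u[i] : x + u[i];
          double q = base_grid ? y + (j - cc) + v[j] : y + v[j];
          for (int ci = 0; ci < Ci; ++ci) {
            double samp = bilin0(a, H, Wd, ci, r, q);
            if (samp == 0.0) continue;
            const double *krow = kp.data() +
                (size_t)Co * (i + (size_t)kh * (j + (size_t)kw * ci));
            for (int co = 0; co < Co; ++co) acc[co] += krow[co] * samp;
          }
        }
      for (int co = 0; co < Co; ++co) ref3(o, H, Wd, x, y, co) = acc[co];
    }
  return out;
}

// [[Rcpp::export]]
List cpp_deform_backward(NumericVector A, NumericVector K, NumericVector u,
                         NumericVector v, bool base_grid, NumericVector gOut) {
  IntegerVector da = A.attr("dim"), dk = K.attr("dim");
  int H = da[0], Wd = da[1], Ci = da[2];
  int kh = dk[0], kw = dk[1], Co = dk[3];
  double cr = (kh - 1) / 2.0, cc = (kw - 1) / 2.0;
  NumericVector gA(A.size()), gK(K.size()), gu(kh), gv(kw);
  gA.attr("dim") = da;
  gK.attr("dim") = dk;
  const double *a = A.begin(), *k = K.begin(), *g = gOut.begin();
  double *pa = gA.begin(), *pk = gK.begin();
  size_t kstep = (size_t)kh * kw * Ci;
  std::vector<double> kp((size_t)Co * kstep), gkp((size_t)Co * kstep, 0.0);
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      kp[(size_t)co + (size_t)Co * t] = k[t + kstep * co];
  std::vector<double> gvv(Co);
  for (int y = 0; y < Wd; ++y)
    for (int x = 0; x < H; ++x) {
      for (int co = 0; co < Co; ++co) gvv[co] = at3(g, H, Wd, x, y, co);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double r = base_grid ? x + (i - cr) + u[i] : x + u[i];
          double q = base_grid ? y + (j - cc) + v[j] : y + v[j];
          for (int ci = 0; ci < Ci; ++ci) {
            double samp = bilin0(a, H, Wd, ci, r, q);
            double dr, dq;
            bilin0_grad_coord(a, H, Wd, ci, r, q, dr, dq);
            size_t t = i + (size_t)kh * (j + (size_t)kw * ci);
            const double *krow = kp.data() + (size_t)Co * t;
            double *gkrow = gkp.data() + (size_t)Co * t;
            double wsum = 0.0;
            for (int co = 0; co < Co; ++co) {
              gkrow[co] += gvv[co] * samp;
              wsum += gvv[co] * krow[co];
            }
            if (wsum != 0.0) {
              bilin0_scatter(pa, H, Wd, ci, r, q, wsum);
              gu[i] += wsum * dr;
              gv[j] += wsum * dq;
            }
          }
        }
    }
  for (size_t t = 0; t < kstep; ++t)
    for (int co = 0; co < Co; ++co)
      pk[t + kstep * co] = gkp[(size_t)co + (size_t)Co * t];
  return List::create(_["input"] = gA, _["kernel"] = gK, _["u"] = gu,
                      _["v"] = gv);
}

// Bilinear resize with half-pixel centers and edge clamping.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector A, int oh, int ow) {
  IntegerVector da = A.attr("dim");
  int H = da[0], Wd = da[1], C = da[2];
  NumericVector out(oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double *a = A.begin();
  double *o = out.begin();
  double sr = (double)H / oh, sc = (double)Wd / ow;
  for (int c = 0; c < C; ++c)
    for (int y = 0; y < ow; ++y)
      for (int x = 0; x < oh; ++x) {
        double r = (x + 0.5) * sr - 0.5, q = (y + 0.5) * sc - 0.5;
        if (r < 0) r = 0; if (r > H - 1) r = H - 1;
        if (q < 0) q = 0; if (q > Wd - 1) q = Wd - 1;
        int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
        int r1 = std::min(r0 + 1, H - 1), q1 = std::min(q0 + 1, Wd - 1);
        double fr = r - r0, fq = q - q0;
        ref3(o, oh, ow, x, y, c) =
            (1 - fr) * ((1 - fq) * at3(a, H, Wd, r0, q0, c) + fq * at3(a, H, Wd, r0, q1, c)) +
            fr * ((1 - fq) * at3(a, H, Wd, r1, q0, c) + fq * at3(a, H, Wd, r1, q1, c));
      }
  return out;
}

// Adjoint of cpp_resize_bilinear (scatter version, same coordinate rule).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gOut, int ih, int iw) {
  IntegerVector dg = gOut.attr("dim");
  int oh = dg[0], ow = dg[1], C = dg[2];
  NumericVector gA(ih * iw * C);
  gA.attr("dim") = IntegerVector::create(ih, iw, C);
  const double *g = gOut.begin();
  double *pa = gA.begin();
  double sr = (double)ih / oh, sc = (double)iw / ow;
  for (int c = 0; c < C; ++c)
    for (int y = 0; y < ow; ++y)
      for (int x = 0; x < oh; ++x) {
        double r = (x + 0.5) * sr - 0.5, q = (y + 0.5) * sc - 0.5;
        if (r < 0) r = 0; if (r > ih - 1) r = ih - 1;
        if (q < 0) q = 0; if (q > iw - 1) q = iw - 1;
        int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
        int r1 = std::min(r0 + 1, ih - 1), q1 = std::min(q0 + 1, iw - 1);
        double fr = r - r0, fq = q - q0;
        double gv = at3(g, oh, ow, x, y, c);
        ref3(pa, ih, iw, r0, q0, c) += (1 - fr) * (1 - fq) * gv;
        ref3(pa, ih, iw, r0, q1, c) += (1 - fr) * fq * gv;
        ref3(pa, ih, iw, r1, q0, c) += fr * (1 - fq) * gv;
        ref3(pa, ih, iw, r1, q1, c) += fr * fq * gv;
      }
  return gA;
}

// Nearest-neighbour resize (used for masks; round-half-up on the same
// half-pixel-center grid as the bilinear resize).
// [[Rcpp::export]]
NumericVector cpp_resize_nearest(NumericVector A, int oh, int ow) {
  IntegerVector da = A.attr("dim");
  int H = da[0], Wd = da[1], C = da[2];
  NumericVector out(oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double *a = A.begin();
  double *o = out.begin();
  double sr = (double)H / oh, sc = (double)Wd / ow;
  for (int c = 0; c < C; ++c)
    for (int y = 0; y < ow; ++y)
      for (int x = 0; x < oh; ++x) {
        int r = (int)std::floor((x + 0.5) * sr);
        int q = (int)std::floor((y + 0.5) * sc);
        if (r > H - 1) r = H - 1;
        if (q > Wd - 1) q = Wd - 1;
        ref3(o, oh, ow, x, y, c) = at3(a, H, Wd, r, q, c);
      }
  return out;
}

// Affine warp by inverse mapping: for each output pixel (r, c) the source
// coordinate is Minv %*% (r, c, 1) in 0-based (row, col) pixel units.
// method: 0 = nearest, 1 = bilinear.  Out-of-frame reads the fill value.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector A, NumericMatrix Minv, int method,
                              double fill) {
  IntegerVector da = A.attr("dim");
  int H = da[0], Wd = da[1], C = da[2];
  NumericVector out(A.size());
  out.attr("dim") = da;
  const double *a = A.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c)
    for (int y = 0; y < Wd; ++y)
      for (int x = 0; x < H; ++x) {
        double r = Minv(0, 0) * x + Minv(0, 1) * y + Minv(0, 2);
        double q = Minv(1, 0) * x + Minv(1, 1) * y + Minv(1, 2);
        double val;
        if (method == 0) {
          int ri = (int)std::lround(r), qi = (int)std::lround(q);
          val = (ri < 0 || ri >= H || qi < 0 || qi >= Wd) ? fill
                                                         : at3(a, H, Wd, ri, qi, c);
        } else {
          if (r < -1 || r > H || q < -1 || q > Wd) {
            val = fill;
          } else {
            val = bilin0(a, H, Wd, c, r, q);
            // blend fill for partially outside samples
            if (fill != 0.0) {
              double cov = 1.0;
              // coverage of the in-frame region under bilinear weights
              int r0 = (int)std::floor(r), q0 = (int)std::floor(q);
              double fr = r - r0, fq = q - q0;
              double wts[4] = {(1 - fr) * (1 - fq), (1 - fr) * fq,
                               fr * (1 - fq), fr * fq};
              int rr[4] = {r0, r0, r0 + 1, r0 + 1};
              int qq[4] = {q0, q0 + 1, q0, q0 + 1};
              cov = 0.0;
              for (int t = 0; t < 4; ++t)
                if (rr[t] >= 0 && rr[t] < H && qq[t] >= 0 && qq[t] < Wd)
                  cov += wts[t];
              val += (1.0 - cov) * fill;
            }
          }
        }
        ref3(o, H, Wd, x, y, c) = val;
      }
  return out;
}

// CRC32 (PNG chunk checksum), returned as a double so the full unsigned
// 32-bit range survives the trip into R.
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// Integer shift with zero fill: out(x, y, c) = A(x + dr, y + dc, c).
// [[Rcpp::export]]
NumericVector cpp_shift_image(NumericVector A, int dr, int dc) {
  IntegerVector da = A.attr("dim");
  int H = da[0], Wd = da[1], C = da[2];
  NumericVector out(A.size());
  out.attr("dim") = da;
  const double *a = A.begin();
  double *o = out.begin();
  int x0 = std::max(0, -dr), x1 = std::min(H, H - dr);
  int y0 = std::max(0, -dc), y1 = std::min(Wd, Wd - dc);
  if (x1 <= x0 || y1 <= y0) return out;
  for (int c = 0; c < C; ++c)
    for (int y = y0; y < y1; ++y) {
      const double *src = a + (size_t)(x0 + dr) + (size_t)H * ((y + dc) + (size_t)Wd * c);
      double *dst = o + (size_t)x0 + (size_t)H * (y + (size_t)Wd * c);
      std::copy(src, src + (x1 - x0), dst);
    }
  return out;
}

// out += w * shift(A, dr, dc), in place on `acc` (used for adjoint scatter).
// [[Rcpp::export]]
void cpp_shift_add(NumericVector acc, NumericVector A, int dr, int dc,
                   double w) {
  IntegerVector da = A.attr("dim");
  int H = da[0], Wd = da[1], C = da[2];
  const double *a = A.begin();
  double *o = acc.begin();
  int x0 = std::max(0, -dr), x1 = std::min(H, H - dr);
  int y0 = std::max(0, -dc), y1 = std::min(Wd, Wd - dc);
  if (x1 <= x0 || y1 <= y0) return;
  for (int c = 0; c < C; ++c)
    for (int y = y0; y < y1; ++y) {
      const double *src = a + (size_t)(x0 + dr) + (size_t)H * ((y + dc) + (size_t)Wd * c);
      double *dst = o + (size_t)x0 + (size_t)H * (y + (size_t)Wd * c);
      for (int x = 0; x < x1 - x0; ++x) dst[x] += w * src[x];
    }
}
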