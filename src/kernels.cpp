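// Low-level sampling kernels for the CNN: im2col/col2im, deformable
// bilinear sampling (forward + backward, including offset gradients),
// bilinear resize, max pooling and reflect-padded rotation.
//
// Tensor layout everywhere: column-major R arrays dim = c(H, W, C, N).
// im2col row index r = c*k*k + kh*k + kw; column index m = ho + Ho*(wo + Wo*n).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

NumericMatrix cpp_im2col(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = k * k * C;
  R_xlen_t M = (R_xlen_t)Ho * Wo * N;
  NumericMatrix cols(R, M);
  double *pc = cols.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; n++)
    for (int wo = 0; wo < Wo; wo++)
      for (int ho = 0; ho < Ho; ho++) {
        R_xlen_t m = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *col = pc + m * R;
        for (int c = 0; c < C; c++)
          for (int kh = 0; kh < k; kh++) {
            int hi = ho * stride - pad + kh;
            bool hok = hi >= 0 && hi < H;
            for (int kw = 0; kw < k; kw++) {
              int wi = wo * stride - pad + kw;
              int r = c * k * k + kh * k + kw;
              col[r] = (hok && wi >= 0 && wi < W)
                         ? px[idx4(hi, wi, c, n, H, W, C)] : 0.0;
            }
          }
      }
  return cols;
}

NumericVector cpp_col2im(NumericMatrix cols, IntegerVector xdim,
                         int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int R = k * k * C;
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *pdx = dx.begin();
  const double *pc = cols.begin();
  for (int n = 0; n < N; n++)
    for (int wo = 0; wo < Wo; wo++)
      for (int ho = 0; ho < Ho; ho++) {
        R_xlen_t m = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double *col = pc + m * R;
        for (int c = 0; c < C; c++)
          for (int kh = 0; kh < k; kh++) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kw = 0; kw < k; kw++) {
              int wi = wo * stride - pad + kw;
              if (wi < 0 || wi >= W) continue;
              pdx[idx4(hi, wi, c, n, H, W, C)] += col[c * k * k + kh * k + kw];
            }
          }
      }
  dx.attr("dim") = xdim;
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with zero outside the map.
static inline double bilin(const double *px, double hh, double ww,
                           int H, int W, int C, int c, int n) {
  int h0 = (int)std::floor(hh), w0 = (int)std::floor(ww);
  double a = hh - h0, b = ww - w0;
  double v = 0.0;
  for (int dh = 0; dh <= 1; dh++)
    for (int dw = 0; dw <= 1; dw++) {
      int h = h0 + dh, w = w0 + dw;
      if (h < 0 || h >= H || w < 0 || w >= W) continue;
      double wt = (dh ? a : 1 - a) * (dw ? b : 1 - b);
      v += wt * px[idx4(h, w, c, n, H, W, C)];
    }
  return v;
}

// offsets: dim c(Ho, Wo, 2*k*k, N); channel 2t = dy, 2t+1 = dx for tap
// t = kh*k + kw (0-based). Raw offsets are clamped elementwise to
// [-cap, cap] before sampling.
NumericMatrix cpp_deform_im2col(NumericVector x, IntegerVector xdim,
                                NumericVector off, int k, int stride,
                                int pad, double cap) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int K = k * k, R = K * C, OC = 2 * K;
  R_xlen_t M = (R_xlen_t)Ho * Wo * N;
  NumericMatrix cols(R, M);
  const double *px = x.begin();
  const double *po = off.begin();
  double *pc = cols.begin();
  for (int n = 0; n < N; n++)
    for (int wo = 0; wo < Wo; wo++)
      for (int ho = 0; ho < Ho; ho++) {
        R_xlen_t m = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *col = pc + m * R;
        for (int kh = 0; kh < k; kh++)
          for (int kw = 0; kw < k; kw++) {
            int t = kh * k + kw;
            double dy = clampd(po[idx4(ho, wo, 2 * t, n, Ho, Wo, OC)], -cap, cap);
            double dxo = clampd(po[idx4(ho, wo, 2 * t + 1, n, Ho, Wo, OC)], -cap, cap);
            double hh = ho * stride - pad + kh + dy;
            double ww = wo * stride - pad + kw + dxo;
            for (int c = 0; c < C; c++)
              col[c * K + t] = bilin(px, hh, ww, H, W, C, c, n);
          }
      }
  return cols;
}

// Backward of deformable sampling: dcols -> gradients w.r.t. x and the raw
// offsets (zero where the raw offset was clamped).
List cpp_deform_backward(NumericMatrix dcols, NumericVector x,
                         IntegerVector xdim, NumericVector off,
                         int k, int stride, int pad, double cap) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int K = k * k, R = K * C, OC = 2 * K;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector doff((R_xlen_t)Ho * Wo * OC * N);
  const double *px = x.begin();
  const double *po = off.begin();
  const double *pd = dcols.begin();
  double *pdx = dx.begin();
  double *pdo = doff.begin();
  for (int n = 0; n < N; n++)
    for (int wo = 0; wo < Wo; wo++)
      for (int ho = 0; ho < Ho; ho++) {
        R_xlen_t m = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double *col = pd + m * R;
        for (int kh = 0; kh < k; kh++)
          for (int kw = 0; kw < k; kw++) {
            int t = kh * k + kw;
            double rdy = po[idx4(ho, wo, 2 * t, n, Ho, Wo, OC)];
            double rdx = po[idx4(ho, wo, 2 * t + 1, n, Ho, Wo, OC)];
            double dy = clampd(rdy, -cap, cap);
            double dxo = clampd(rdx, -cap, cap);
            double hh = ho * stride - pad + kh + dy;
            double ww = wo * stride - pad + kw + dxo;
            int h0 = (int)std::floor(hh), w0 = (int)std::floor(ww);
            double a = hh - h0, b = ww - w0;
            double gdy = 0.0, gdx = 0.0;
            for (int c = 0; c < C; c++) {
              double g = col[c * K + t];
              if (g == 0.0) continue;
              double x00 = 0, x01 = 0, x10 = 0, x11 = 0;
              if (h0 >= 0 && h0 < H) {
                if (w0 >= 0 && w0 < W) x00 = px[idx4(h0, w0, c, n, H, W, C)];
                if (w0 + 1 >= 0 && w0 + 1 < W) x01 = px[idx4(h0, w0 + 1, c, n, H, W, C)];
              }
              if (h0 + 1 >= 0 && h0 + 1 < H) {
                if (w0 >= 0 && w0 < W) x10 = px[idx4(h0 + 1, w0, c, n, H, W, C)];
                if (w0 + 1 >= 0 && w0 + 1 < W) x11 = px[idx4(h0 + 1, w0 + 1, c, n, H, W, C)];
              }
              // d(sample)/d(input) scatter
              if (h0 >= 0 && h0 < H) {
                if (w0 >= 0 && w0 < W)
                  pdx[idx4(h0, w0, c, n, H, W, C)] += g * (1 - a) * (1 - b);
                if (w0 + 1 >= 0 && w0 + 1 < W)
                  pdx[idx4(h0, w0 + 1, c, n, H, W, C)] += g * (1 - a) * b;
              }
              if (h0 + 1 >= 0 && h0 + 1 < H) {
                if (w0 >= 0 && w0 < W)
                  pdx[idx4(h0 + 1, w0, c, n, H, W, C)] += g * a * (1 - b);
                if (w0 + 1 >= 0 && w0 + 1 < W)
                  pdx[idx4(h0 + 1, w0 + 1, c, n, H, W, C)] += g * a * b;
              }
              gdy += g * (-(1 - b) * x00 - b * x01 + (1 - b) * x10 + b * x11);
              gdx += g * (-(1 - a) * x00 + (1 - a) * x01 - a * x10 + a * x11);
            }
            if (std::fabs(rdy) < cap)
              pdo[idx4(ho, wo, 2 * t, n, Ho, Wo, OC)] = gdy;
            if (std::fabs(rdx) < cap)
              pdo[idx4(ho, wo, 2 * t + 1, n, Ho, Wo, OC)] = gdx;
          }
      }
  dx.attr("dim") = xdim;
  doff.attr("dim") = IntegerVector::create(Ho, Wo, OC, N);
  return List::create(_["dx"] = dx, _["doff"] = doff);
}

// Half-pixel-centre bilinear resize: src = (dst + 0.5) * S/So - 0.5,
// clamped to the valid range (edge replication at borders).
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int Ho, int Wo) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++) {
        double ws = clampd((wo + 0.5) * sw - 0.5, 0, W - 1);
        int w0 = (int)std::floor(ws);
        int w1 = w0 + 1 < W ? w0 + 1 : w0;
        double b = ws - w0;
        for (int ho = 0; ho < Ho; ho++) {
          double hs = clampd((ho + 0.5) * sh - 0.5, 0, H - 1);
          int h0 = (int)std::floor(hs);
          int h1 = h0 + 1 < H ? h0 + 1 : h0;
          double a = hs - h0;
          double v = (1 - a) * (1 - b) * px[idx4(h0, w0, c, n, H, W, C)]
                   + (1 - a) * b * px[idx4(h0, w1, c, n, H, W, C)]
                   + a * (1 - b) * px[idx4(h1, w0, c, n, H, W, C)]
                   + a * b * px[idx4(h1, w1, c, n, H, W, C)];
          py[idx4(ho, wo, c, n, Ho, Wo, C)] = v;
        }
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// Transpose of cpp_resize_bilinear (gradient scatter).
NumericVector cpp_resize_bilinear_backward(NumericVector dy, IntegerVector ydim,
                                           int H, int W) {
  int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++) {
        double ws = clampd((wo + 0.5) * sw - 0.5, 0, W - 1);
        int w0 = (int)std::floor(ws);
        int w1 = w0 + 1 < W ? w0 + 1 : w0;
        double b = ws - w0;
        for (int ho = 0; ho < Ho; ho++) {
          double hs = clampd((ho + 0.5) * sh - 0.5, 0, H - 1);
          int h0 = (int)std::floor(hs);
          int h1 = h0 + 1 < H ? h0 + 1 : h0;
          double a = hs - h0;
          double g = pdy[idx4(ho, wo, c, n, Ho, Wo, C)];
          pdx[idx4(h0, w0, c, n, H, W, C)] += g * (1 - a) * (1 - b);
          pdx[idx4(h0, w1, c, n, H, W, C)] += g * (1 - a) * b;
          pdx[idx4(h1, w0, c, n, H, W, C)] += g * a * (1 - b);
          pdx[idx4(h1, w1, c, n, H, W, C)] += g * a * b;
        }
      }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Box-average reduction by integer factor f (anti-alias prefilter).
// Trailing rows/cols not divisible by f are folded into the last cell.
NumericVector cpp_box_reduce(NumericVector x, IntegerVector xdim, int f) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / f, Wo = W / f;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++) {
        int w1 = wo * f, w2 = (wo == Wo - 1) ? W : (wo + 1) * f;
        for (int ho = 0; ho < Ho; ho++) {
          int h1 = ho * f, h2 = (ho == Ho - 1) ? H : (ho + 1) * f;
          double s = 0.0;
          for (int w = w1; w < w2; w++)
            for (int h = h1; h < h2; h++)
              s += px[idx4(h, w, c, n, H, W, C)];
          py[idx4(ho, wo, c, n, Ho, Wo, C)] = s / ((h2 - h1) * (w2 - w1));
        }
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

List cpp_maxpool(NumericVector x, IntegerVector xdim, int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++)
      for (int wo = 0; wo < Wo; wo++)
        for (int ho = 0; ho < Ho; ho++) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kh = 0; kh < k; kh++) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            for (int kw = 0; kw < k; kw++) {
              int wi = wo * stride - pad + kw;
              if (wi < 0 || wi >= W) continue;
              R_xlen_t i = idx4(hi, wi, c, n, H, W, C);
              if (px[i] > best) { best = px[i]; besti = i; }
            }
          }
          R_xlen_t o = idx4(ho, wo, c, n, Ho, Wo, C);
          py[o] = best;
          pa[o] = (int)besti;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector argmax,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const int *pa = argmax.begin();
  R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; i++) pdx[pa[i]] += pdy[i];
  dx.attr("dim") = xdim;
  return dx;
}

static inline int reflect101(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n - 2;
  i = ((i % p) + p) % p;
  return i < n ? i : p - i;
}

// Rotate an (H, W, C) image about its centre by `angle` degrees
// (counter-clockwise), bilinear sampling with reflect-101 padding,
// output size unchanged.
NumericVector cpp_rotate_reflect(NumericVector img, IntegerVector dim, double angle) {
  int H = dim[0], W = dim[1], C = dim[2];
  NumericVector out((R_xlen_t)H * W * C);
  const double *px = img.begin();
  double *py = out.begin();
  double th = angle * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int c = 0; c < C; c++)
    for (int w = 0; w < W; w++)
      for (int h = 0; h < H; h++) {
        // inverse map: source coords of destination pixel
        double yr = h - cy, xr = w - cx;
        double hs = ct * yr + st * xr + cy;
        double ws = -st * yr + ct * xr + cx;
        int h0 = (int)std::floor(hs), w0 = (int)std::floor(ws);
        double a = hs - h0, b = ws - w0;
        double v = 0.0;
        for (int dh = 0; dh <= 1; dh++)
          for (int dw = 0; dw <= 1; dw++) {
            int hr = reflect101(h0 + dh, H);
            int wr = reflect101(w0 + dw, W);
            double wt = (dh ? a : 1 - a) * (dw ? b : 1 - b);
            v += wt * px[(R_xlen_t)hr + (R_xlen_t)H * (wr + (R_xlen_t)W * c)];
          }
        py[(R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * c)] = v;
      }
  out.attr("dim") = dim;
  return out;
}
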