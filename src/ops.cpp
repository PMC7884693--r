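#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with edge clamping; coordinates are 0-based (row, col).
static inline double sample_clamp(const NumericMatrix &img, double r, double c) {
  int h = img.nrow(), w = img.ncol();
  if (r < 0) r = 0; if (r > h - 1) r = h - 1;
  if (c < 0) c = 0; if (c > w - 1) c = w - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < h ? r0 + 1 : r0;
  int c1 = c0 + 1 < w ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Bilinear sample returning `fill` outside the source raster.
static inline double sample_fill(const NumericMatrix &img, double r, double c,
                                 double fill) {
  int h = img.nrow(), w = img.ncol();
  if (r < 0 || c < 0 || r > h - 1 || c > w - 1) return fill;
  return sample_clamp(img, r, c);
}

// Projective warp. Hinv maps destination (x, y, 1) to source homogeneous
// coordinates; x = column, y = row, both 0-based pixel centres.
// [[Rcpp::export]]
NumericMatrix cpp_warp_projective(NumericMatrix img, NumericMatrix Hinv,
                                  int out_h, int out_w, double fill,
                                  bool clamp_edges) {
  NumericMatrix out(out_h, out_w);
  for (int r = 0; r < out_h; ++r) {
    for (int c = 0; c < out_w; ++c) {
      double x = c, y = r;
      double sx = Hinv(0, 0) * x + Hinv(0, 1) * y + Hinv(0, 2);
      double sy = Hinv(1, 0) * x + Hinv(1, 1) * y + Hinv(1, 2);
      double sw = Hinv(2, 0) * x + Hinv(2, 1) * y + Hinv(2, 2);
      sx /= sw; sy /= sw;
      out(r, c) = clamp_edges ? sample_clamp(img, sy, sx)
                              : sample_fill(img, sy, sx, fill);
    }
  }
  return out;
}

// Bilinear resize with pixel-centre alignment.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  NumericMatrix out(out_h, out_w);
  double sr = (double)img.nrow() / out_h, sc = (double)img.ncol() / out_w;
  for (int r = 0; r < out_h; ++r) {
    double src_r = (r + 0.5) * sr - 0.5;
    for (int c = 0; c < out_w; ++c) {
      double src_c = (c + 0.5) * sc - 0.5;
      out(r, c) = sample_clamp(img, src_r, src_c);
    }
  }
  return out;
}

// 2-D convolution with reflection (mirror) border handling.
// [[Rcpp::export]]
NumericMatrix cpp_convolve2_reflect(NumericMatrix img, NumericMatrix kernel) {
  int h = img.nrow(), w = img.ncol();
  int kh = kernel.nrow(), kw = kernel.ncol();
  int cr = kh / 2, cc = kw / 2;
  NumericMatrix out(h, w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      double acc = 0.0;
      for (int i = 0; i < kh; ++i) {
        int rr = r + i - cr;
        if (rr < 0) rr = -rr - 1;
        if (rr >= h) rr = 2 * h - rr - 1;
        for (int j = 0; j < kw; ++j) {
          int ccx = c + j - cc;
          if (ccx < 0) ccx = -ccx - 1;
          if (ccx >= w) ccx = 2 * w - ccx - 1;
          acc += img(rr, ccx) * kernel(i, j);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Radon transform: line integrals along rays, one column per angle.
// Detector axis t and ray parameter s both use unit (1 pixel) spacing;
// t = 0 corresponds to a ray through the image centre.
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector angles, int ndet) {
  int h = img.nrow(), w = img.ncol();
  double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  double t0 = (ndet - 1) / 2.0;
  int na = angles.size();
  NumericMatrix sino(ndet, na);
  for (int k = 0; k < na; ++k) {
    double ct = std::cos(angles[k]), st = std::sin(angles[k]);
    for (int ti = 0; ti < ndet; ++ti) {
      double t = ti - t0;
      double acc = 0.0;
      for (int si = 0; si < ndet; ++si) {
        double s = si - t0;
        double x = cx + t * ct - s * st;
        double y = cy + t * st + s * ct;
        if (x < 0 || y < 0 || x > w - 1 || y > h - 1) continue;
        acc += sample_clamp(img, y, x);
      }
      sino(ti, k) = acc;
    }
  }
  return sino;
}

// Back-projection of a (ramp-filtered) sinogram onto an h x w grid.
// Output is scaled by pi / n_angles, the FBP quadrature weight over [0, pi).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles,
                              int h, int w) {
  int ndet = sino.nrow(), na = angles.size();
  double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  double t0 = (ndet - 1) / 2.0;
  NumericMatrix out(h, w);
  for (int k = 0; k < na; ++k) {
    double ct = std::cos(angles[k]), st = std::sin(angles[k]);
    for (int r = 0; r < h; ++r) {
      double y = r - cy;
      for (int c = 0; c < w; ++c) {
        double x = c - cx;
        double t = x * ct + y * st + t0;
        if (t < 0 || t > ndet - 1) continue;
        int i0 = (int)std::floor(t);
        int i1 = i0 + 1 < ndet ? i0 + 1 : i0;
        double f = t - i0;
        out(r, c) += (1 - f) * sino(i0, k) + f * sino(i1, k);
      }
    }
  }
  double scale = M_PI / (double)na;
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) out(r, c) *= scale;
  return out;
}
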