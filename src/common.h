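#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

// Row-major grayscale image buffer. R matrices are column-major with
// rows = y (image row) and cols = x, so from_R/to_R transpose the layout
// but not the indexing convention: at(y, x) always means row y, column x.
struct Img {
  int h = 0, w = 0;
  std::vector<double> d;
  Img() = default;
  Img(int h_, int w_, double v = 0.0) : h(h_), w(w_), d((size_t)h_ * w_, v) {}
  inline double& at(int y, int x) { return d[(size_t)y * w + x]; }
  inline double at(int y, int x) const { return d[(size_t)y * w + x]; }
  // clamped (replicate-border) access
  inline double atc(int y, int x) const {
    y = y < 0 ? 0 : (y >= h ? h - 1 : y);
    x = x < 0 ? 0 : (x >= w ? w - 1 : x);
    return d[(size_t)y * w + x];
  }
};

inline Img from_R(const Rcpp::NumericMatrix& m) {
  Img im(m.nrow(), m.ncol());
  for (int x = 0; x < im.w; ++x)
    for (int y = 0; y < im.h; ++y) im.at(y, x) = m(y, x);
  return im;
}

inline Rcpp::NumericMatrix to_R(const Img& im) {
  Rcpp::NumericMatrix m(im.h, im.w);
  for (int x = 0; x < im.w; ++x)
    for (int y = 0; y < im.h; ++y) m(y, x) = im.at(y, x);
  return m;
}

// bilinear sample with replicate border; (x, y) in pixel-center coordinates
inline double bilinear(const Img& im, double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double v00 = im.atc(y0, x0), v01 = im.atc(y0, x0 + 1);
  double v10 = im.atc(y0 + 1, x0), v11 = im.atc(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// separable Gaussian blur, replicate borders; sx/sy <= 0 skips that axis
void gauss_blur_inplace(Img& im, double sx, double sy);
inline Img gauss_blur(const Img& im, double sx, double sy) {
  Img out = im;
  gauss_blur_inplace(out, sx, sy);
  return out;
}

// decimate by 2 keeping even pixels: out(y, x) = in(2y, 2x)
inline Img downsample2(const Img& im) {
  Img out((im.h + 1) / 2, (im.w + 1) / 2);
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x) out.at(y, x) = im.at(2 * y, 2 * x);
  return out;
}

Img resize_bilinear(const Img& im, int nh, int nw);

struct KP {
  double x, y;       // location in the coordinates of the image given to the detector
  double size;       // characteristic scale, pixels
  double angle;      // orientation, radians
  double response;   // detector response used for ranking
};

Rcpp::List kp_result(const std::vector<KP>& kps, Rcpp::RObject desc);
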