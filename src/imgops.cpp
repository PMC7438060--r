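#include "common.h"
using namespace Rcpp;

void gauss_blur_inplace(Img& im, double sx, double sy) {
  auto kernel = [](double s) {
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (auto& v : k) v /= sum;
    return k;
  };
  if (sx > 0) {
    std::vector<double> k = kernel(sx);
    int r = ((int)k.size() - 1) / 2;
    Img tmp(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
      for (int x = 0; x < im.w; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) acc += k[i + r] * im.atc(y, x + i);
        tmp.at(y, x) = acc;
      }
    im = std::move(tmp);
  }
  if (sy > 0) {
    std::vector<double> k = kernel(sy);
    int r = ((int)k.size() - 1) / 2;
    Img tmp(im.h, im.w);
    for (int y = 0; y < im.h; ++y)
      for (int x = 0; x < im.w; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) acc += k[i + r] * im.atc(y + i, x);
        tmp.at(y, x) = acc;
      }
    im = std::move(tmp);
  }
}

Img resize_bilinear(const Img& im, int nh, int nw) {
  Img out(nh, nw);
  double sy = (double)im.h / nh, sx = (double)im.w / nw;
  for (int y = 0; y < nh; ++y)
    for (int x = 0; x < nw; ++x)
      out.at(y, x) = bilinear(im, (x + 0.5) * sx - 0.5, (y + 0.5) * sy - 0.5);
  return out;
}

Rcpp::List kp_result(const std::vector<KP>& kps, Rcpp::RObject desc) {
  int n = kps.size();
  NumericMatrix k(n, 5);
  for (int i = 0; i < n; ++i) {
    k(i, 0) = kps[i].x;
    k(i, 1) = kps[i].y;
    k(i, 2) = kps[i].size;
    k(i, 3) = kps[i].angle;
    k(i, 4) = kps[i].response;
  }
  colnames(k) = CharacterVector::create("x", "y", "scale", "orientation", "response");
  return List::create(Named("keypoints") = k, Named("descriptors") = desc);
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sx, double sy) {
  Img im = from_R(img);
  gauss_blur_inplace(im, sx, sy);
  return to_R(im);
}

// Warp with the *inverse* map: minv is 2x3 sending output (x, y) to input
// coordinates.  interp: 0 nearest, 1 bilinear.  Samples falling outside the
// input frame become bg.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericMatrix minv,
                              int out_h, int out_w, int interp, double bg) {
  Img im = from_R(img);
  double a = minv(0, 0), b = minv(0, 1), e = minv(0, 2);
  double c = minv(1, 0), d = minv(1, 1), f = minv(1, 2);
  NumericMatrix out(out_h, out_w);
  for (int y = 0; y < out_h; ++y)
    for (int x = 0; x < out_w; ++x) {
      double xi = a * x + b * y + e;
      double yi = c * x + d * y + f;
      if (interp == 0) {
        int xr = (int)std::lround(xi), yr = (int)std::lround(yi);
        out(y, x) = (xr < 0 || xr >= im.w || yr < 0 || yr >= im.h) ? bg : im.at(yr, xr);
      } else {
        out(y, x) = (xi < 0 || xi > im.w - 1 || yi < 0 || yi > im.h - 1)
                        ? bg
                        : bilinear(im, xi, yi);
      }
    }
  return out;
}

// L1 mask disagreement: warp the moving mask into the template frame with
// nearest-neighbour sampling (out-of-frame -> 0) and sum |warped - template|.
// minv maps template (x, y) to moving coordinates.
// [[Rcpp::export]]
double cpp_l1_mask_score(NumericMatrix moving_mask, NumericMatrix template_mask,
                         NumericMatrix minv) {
  Img mv = from_R(moving_mask);
  double a = minv(0, 0), b = minv(0, 1), e = minv(0, 2);
  double c = minv(1, 0), d = minv(1, 1), f = minv(1, 2);
  int H = template_mask.nrow(), W = template_mask.ncol();
  double score = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double xi = a * x + b * y + e;
      double yi = c * x + d * y + f;
      int xr = (int)std::lround(xi), yr = (int)std::lround(yi);
      double v = (xr < 0 || xr >= mv.w || yr < 0 || yr >= mv.h) ? 0.0 : mv.at(yr, xr);
      score += std::fabs(v - template_mask(y, x));
    }
  return score;
}

// CLAHE with the OpenCV clip-limit convention: the per-bin ceiling is
// max(1, clip_limit * tile_area / 256); clipped mass is redistributed
// uniformly; tile LUTs are blended bilinearly at each pixel.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(NumericMatrix img, int nx, int ny, double clip_limit) {
  int H = img.nrow(), W = img.ncol();
  int tw = (W + nx - 1) / nx, th = (H + ny - 1) / ny;
  std::vector<std::vector<double>> lut((size_t)nx * ny, std::vector<double>(256, 0.0));
  for (int ty = 0; ty < ny; ++ty)
    for (int tx = 0; tx < nx; ++tx) {
      int x0 = tx * tw, x1 = std::min(W, x0 + tw);
      int y0 = ty * th, y1 = std::min(H, y0 + th);
      int area = (x1 - x0) * (y1 - y0);
      std::vector<double> hist(256, 0.0);
      for (int y = y0; y < y1; ++y)
        for (int x = x0; x < x1; ++x) {
          int v = (int)std::lround(img(y, x));
          v = v < 0 ? 0 : (v > 255 ? 255 : v);
          hist[v] += 1;
        }
      double clip = std::max(1.0, clip_limit * area / 256.0);
      double excess = 0;
      for (int i = 0; i < 256; ++i)
        if (hist[i] > clip) {
          excess += hist[i] - clip;
          hist[i] = clip;
        }
      double add = excess / 256.0;
      for (int i = 0; i < 256; ++i) hist[i] += add;
      double cdf = 0;
      std::vector<double>& L = lut[(size_t)ty * nx + tx];
      for (int i = 0; i < 256; ++i) {
        cdf += hist[i];
        L[i] = 255.0 * cdf / area;
      }
    }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int v = (int)std::lround(img(y, x));
      v = v < 0 ? 0 : (v > 255 ? 255 : v);
      double gx = (x - 0.5 * (tw - 1)) / tw;   // tile-grid coordinates
      double gy = (y - 0.5 * (th - 1)) / th;
      int tx0 = (int)std::floor(gx), ty0 = (int)std::floor(gy);
      double fx = gx - tx0, fy = gy - ty0;
      int txa = std::min(nx - 1, std::max(0, tx0));
      int txb = std::min(nx - 1, std::max(0, tx0 + 1));
      int tya = std::min(ny - 1, std::max(0, ty0));
      int tyb = std::min(ny - 1, std::max(0, ty0 + 1));
      double v00 = lut[(size_t)tya * nx + txa][v], v01 = lut[(size_t)tya * nx + txb][v];
      double v10 = lut[(size_t)tyb * nx + txa][v], v11 = lut[(size_t)tyb * nx + txb][v];
      double r = (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
      out(y, x) = r < 0 ? 0 : (r > 255 ? 255 : r);
    }
  return out;
}

// 8-connected labelling of a binary image (nonzero = foreground).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.push_back({y, x});
      lab(y, x) = next;
      while (!stack.empty()) {
        auto [cy, cx] = stack.back();
        stack.pop_back();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nyy = cy + dy, nxx = cx + dx;
            if (nyy < 0 || nyy >= H || nxx < 0 || nxx >= W) continue;
            if (mask(nyy, nxx) != 0 && lab(nyy, nxx) == 0) {
              lab(nyy, nxx) = next;
              stack.push_back({nyy, nxx});
            }
          }
      }
    }
  return lab;
}
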