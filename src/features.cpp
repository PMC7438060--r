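#include "common.h"
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ------------------------------------------------------------------
// shared helpers
// ------------------------------------------------------------------

// up to max_peaks dominant gradient orientations around (x, y) at scale sigma
static std::vector<double> dominant_orientations(const Img& im, double x, double y,
                                                 double sigma, int max_peaks) {
  const int nb = 36;
  std::vector<double> hist(nb, 0.0);
  double sw = 1.5 * sigma;
  int r = std::max(2, (int)std::lround(3.0 * sw));
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= im.w - 1 || py < 1 || py >= im.h - 1) continue;
      double gx = 0.5 * (im.at(py, px + 1) - im.at(py, px - 1));
      double gy = 0.5 * (im.at(py + 1, px) - im.at(py - 1, px));
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag <= 0) continue;
      double wgt = std::exp(-0.5 * (dx * dx + dy * dy) / (sw * sw));
      double ang = std::atan2(gy, gx);
      int bin = (int)std::floor((ang + PI_) / (2 * PI_) * nb);
      bin = std::min(nb - 1, std::max(0, bin));
      hist[bin] += mag * wgt;
    }
  for (int it = 0; it < 2; ++it) {
    std::vector<double> s(nb);
    for (int i = 0; i < nb; ++i)
      s[i] = (hist[(i + nb - 1) % nb] + hist[i] + hist[(i + 1) % nb]) / 3.0;
    hist = s;
  }
  double mx = *std::max_element(hist.begin(), hist.end());
  std::vector<double> out;
  if (mx <= 0) {
    out.push_back(0.0);
    return out;
  }
  for (int i = 0; i < nb; ++i) {
    double l = hist[(i + nb - 1) % nb], c = hist[i], rr = hist[(i + 1) % nb];
    if (c >= l && c >= rr && c >= 0.8 * mx) {
      double denom = l - 2 * c + rr;
      double off = denom != 0 ? 0.5 * (l - rr) / denom : 0.0;
      double ang = ((i + 0.5 + off) / nb) * 2 * PI_ - PI_;
      out.push_back(ang);
      if ((int)out.size() >= max_peaks) break;
    }
  }
  if (out.empty()) out.push_back(0.0);
  return out;
}

// Gaussian scale-space: per octave `nlev` images with relative blur
// sigma0 * 2^(i/spo); octaves are decimated by 2.
struct Octave {
  std::vector<Img> g;
  int oct;
};

static std::vector<Octave> build_gauss_pyramid(const Img& base0, double sigma0,
                                               int spo, int nlev, int max_oct) {
  Img base = base0;
  double init = 0.5;  // assumed blur of the input
  double d = sigma0 * sigma0 - init * init;
  if (d > 0) gauss_blur_inplace(base, std::sqrt(d), std::sqrt(d));
  std::vector<Octave> pyr;
  for (int o = 0; o < max_oct; ++o) {
    if (std::min(base.h, base.w) < 16) break;
    Octave oc;
    oc.oct = o;
    oc.g.push_back(base);
    for (int i = 1; i < nlev; ++i) {
      double s_prev = sigma0 * std::pow(2.0, (i - 1.0) / spo);
      double s_cur = sigma0 * std::pow(2.0, (double)i / spo);
      double sd = std::sqrt(s_cur * s_cur - s_prev * s_prev);
      oc.g.push_back(gauss_blur(oc.g.back(), sd, sd));
    }
    pyr.push_back(oc);
    base = downsample2(pyr.back().g[spo]);  // level with sigma = 2*sigma0
  }
  return pyr;
}

// quadratic sub-pixel refinement on a single response map; returns false if
// the extremum is rejected (shifts too far)
static bool refine2d(const Img& m, int y, int x, double& ox, double& oy,
                     double& val) {
  double dx = 0.5 * (m.at(y, x + 1) - m.at(y, x - 1));
  double dy = 0.5 * (m.at(y + 1, x) - m.at(y - 1, x));
  double dxx = m.at(y, x + 1) - 2 * m.at(y, x) + m.at(y, x - 1);
  double dyy = m.at(y + 1, x) - 2 * m.at(y, x) + m.at(y - 1, x);
  double dxy = 0.25 * (m.at(y + 1, x + 1) + m.at(y - 1, x - 1) -
                       m.at(y + 1, x - 1) - m.at(y - 1, x + 1));
  double det = dxx * dyy - dxy * dxy;
  if (std::fabs(det) < 1e-14) {
    ox = oy = 0;
    val = m.at(y, x);
    return true;
  }
  double sx = -(dyy * dx - dxy * dy) / det;
  double sy = -(-dxy * dx + dxx * dy) / det;
  if (std::fabs(sx) > 1.5 || std::fabs(sy) > 1.5) return false;
  sx = std::max(-0.5, std::min(0.5, sx));
  sy = std::max(-0.5, std::min(0.5, sy));
  ox = sx;
  oy = sy;
  val = m.at(y, x) + 0.5 * (dx * sx + dy * sy);
  return true;
}

struct RawKP {
  int oct, lev;
  double x, y;  // octave coordinates, sub-pixel
  double response;
};

static void sort_cap(std::vector<RawKP>& v, int cap) {
  std::sort(v.begin(), v.end(), [](const RawKP& a, const RawKP& b) {
    if (std::fabs(a.response) != std::fabs(b.response))
      return std::fabs(a.response) > std::fabs(b.response);
    if (a.oct != b.oct) return a.oct < b.oct;
    if (a.lev != b.lev) return a.lev < b.lev;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  if ((int)v.size() > cap) v.resize(cap);
}

// pack a vector<vector<uint8>> into a RawMatrix with one descriptor per row
static RawMatrix pack_bits(const std::vector<std::vector<uint8_t>>& rows, int nbytes) {
  RawMatrix m(rows.size(), nbytes);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < nbytes; ++j) m(i, j) = rows[i][j];
  return m;
}

// ------------------------------------------------------------------
// SIFT-style backend: DoG extrema + 4x4x8 gradient histogram descriptor
// ------------------------------------------------------------------

static std::vector<double> sift_descriptor(const Img& im, double x, double y,
                                           double sigma, double angle) {
  const int d = 4, nb = 8;
  double hw = 3.0 * sigma;
  double radius = hw * (d + 1) * 0.5 * std::sqrt(2.0);
  double ca = std::cos(angle), sa = std::sin(angle);
  std::vector<double> desc(d * d * nb, 0.0);
  int r = (int)std::lround(radius);
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double rx = (ca * dx + sa * dy) / hw;
      double ry = (-sa * dx + ca * dy) / hw;
      double cbx = rx + d / 2 - 0.5, cby = ry + d / 2 - 0.5;
      if (cbx <= -1 || cbx >= d || cby <= -1 || cby >= d) continue;
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= im.w - 1 || py < 1 || py >= im.h - 1) continue;
      double gx = 0.5 * (im.at(py, px + 1) - im.at(py, px - 1));
      double gy = 0.5 * (im.at(py + 1, px) - im.at(py - 1, px));
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag <= 0) continue;
      double theta = std::atan2(gy, gx) - angle;
      while (theta < 0) theta += 2 * PI_;
      while (theta >= 2 * PI_) theta -= 2 * PI_;
      double ob = theta / (2 * PI_) * nb;
      double wgt = std::exp(-(rx * rx + ry * ry) / (0.5 * d * d));
      int x0 = (int)std::floor(cbx), y0 = (int)std::floor(cby), o0 = (int)std::floor(ob);
      double fx = cbx - x0, fy = cby - y0, fo = ob - o0;
      if (o0 >= nb) o0 -= nb;
      for (int iy = 0; iy <= 1; ++iy)
        for (int ix = 0; ix <= 1; ++ix) {
          int bx = x0 + ix, by = y0 + iy;
          if (bx < 0 || bx >= d || by < 0 || by >= d) continue;
          double wxy = wgt * mag * (ix ? fx : 1 - fx) * (iy ? fy : 1 - fy);
          for (int io = 0; io <= 1; ++io) {
            int bo = (o0 + io) % nb;
            desc[(by * d + bx) * nb + bo] += wxy * (io ? fo : 1 - fo);
          }
        }
    }
  double nrm = 0;
  for (double v : desc) nrm += v * v;
  nrm = std::sqrt(nrm);
  if (nrm > 0) {
    for (auto& v : desc) v = std::min(0.2, v / nrm);
    nrm = 0;
    for (double v : desc) nrm += v * v;
    nrm = std::sqrt(nrm);
    if (nrm > 0)
      for (auto& v : desc) v /= nrm;
  }
  return desc;
}

// [[Rcpp::export]]
List cpp_sift(NumericMatrix img, double contrast_thresh, double edge_ratio,
              int max_keypoints) {
  Img base = from_R(img);
  for (auto& v : base.d) v /= 255.0;
  const int spo = 3;
  const double sigma0 = 1.6;
  std::vector<Octave> pyr = build_gauss_pyramid(base, sigma0, spo, spo + 3, 4);
  std::vector<RawKP> raw;
  std::vector<std::vector<Img>> dogs(pyr.size());
  for (size_t o = 0; o < pyr.size(); ++o) {
    const auto& g = pyr[o].g;
    std::vector<Img>& dog = dogs[o];
    for (int i = 0; i + 1 < (int)g.size(); ++i) {
      Img d(g[i].h, g[i].w);
      for (size_t k = 0; k < d.d.size(); ++k) d.d[k] = g[i + 1].d[k] - g[i].d[k];
      dog.push_back(std::move(d));
    }
    for (int i = 1; i <= spo; ++i) {
      const Img& c = dog[i];
      for (int y = 1; y < c.h - 1; ++y)
        for (int x = 1; x < c.w - 1; ++x) {
          double v = c.at(y, x);
          if (std::fabs(v) < 0.5 * contrast_thresh) continue;
          bool mx = true, mn = true;
          for (int l = i - 1; l <= i + 1 && (mx || mn); ++l)
            for (int dy = -1; dy <= 1 && (mx || mn); ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (l == i && dy == 0 && dx == 0) continue;
                double nvb = dog[l].at(y + dy, x + dx);
                if (nvb >= v) mx = false;
                if (nvb <= v) mn = false;
                if (!mx && !mn) break;
              }
          if (!mx && !mn) continue;
          double ox, oy, val;
          if (!refine2d(c, y, x, ox, oy, val)) continue;
          if (std::fabs(val) < contrast_thresh) continue;
          double dxx = c.at(y, x + 1) - 2 * v + c.at(y, x - 1);
          double dyy = c.at(y + 1, x) - 2 * v + c.at(y - 1, x);
          double dxy = 0.25 * (c.at(y + 1, x + 1) + c.at(y - 1, x - 1) -
                               c.at(y + 1, x - 1) - c.at(y - 1, x + 1));
          double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
          double er = edge_ratio;
          if (det <= 0 || tr * tr * er >= (er + 1) * (er + 1) * det) continue;
          raw.push_back({(int)o, i, x + ox, y + oy, val});
        }
    }
  }
  sort_cap(raw, max_keypoints);
  std::vector<KP> kps;
  std::vector<std::vector<double>> descs;
  for (const auto& rk : raw) {
    double s_rel = sigma0 * std::pow(2.0, (double)rk.lev / spo);
    const Img& gim = pyr[rk.oct].g[rk.lev];
    double scale = std::pow(2.0, rk.oct);
    for (double ang : dominant_orientations(gim, rk.x, rk.y, s_rel, 2)) {
      kps.push_back({rk.x * scale, rk.y * scale, s_rel * scale, ang,
                     std::fabs(rk.response)});
      descs.push_back(sift_descriptor(gim, rk.x, rk.y, s_rel, ang));
    }
  }
  NumericMatrix dm(descs.size(), 128);
  for (size_t i = 0; i < descs.size(); ++i)
    for (int j = 0; j < 128; ++j) dm(i, j) = descs[i][j];
  return kp_result(kps, dm);
}

// ------------------------------------------------------------------
// Hessian-determinant detector, shared by the SURF- and AKAZE-style backends
// ------------------------------------------------------------------

static std::vector<RawKP> detect_doh(const std::vector<Octave>& pyr, int spo,
                                     double sigma0, double thresh) {
  std::vector<RawKP> raw;
  for (size_t o = 0; o < pyr.size(); ++o) {
    const auto& g = pyr[o].g;
    std::vector<Img> resp;
    for (size_t i = 0; i < g.size(); ++i) {
      double s = sigma0 * std::pow(2.0, (double)i / spo);
      double s4 = s * s * s * s;
      Img r(g[i].h, g[i].w, 0.0);
      for (int y = 1; y < r.h - 1; ++y)
        for (int x = 1; x < r.w - 1; ++x) {
          double lxx = g[i].at(y, x + 1) - 2 * g[i].at(y, x) + g[i].at(y, x - 1);
          double lyy = g[i].at(y + 1, x) - 2 * g[i].at(y, x) + g[i].at(y - 1, x);
          double lxy = 0.25 * (g[i].at(y + 1, x + 1) + g[i].at(y - 1, x - 1) -
                               g[i].at(y + 1, x - 1) - g[i].at(y - 1, x + 1));
          r.at(y, x) = s4 * (lxx * lyy - lxy * lxy);
        }
      resp.push_back(std::move(r));
    }
    for (int i = 1; i + 1 < (int)resp.size(); ++i) {
      const Img& c = resp[i];
      for (int y = 1; y < c.h - 1; ++y)
        for (int x = 1; x < c.w - 1; ++x) {
          double v = c.at(y, x);
          if (v < thresh) continue;
          bool mx = true;
          for (int l = i - 1; l <= i + 1 && mx; ++l)
            for (int dy = -1; dy <= 1 && mx; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (l == i && dy == 0 && dx == 0) continue;
                if (resp[l].at(y + dy, x + dx) >= v) {
                  mx = false;
                  break;
                }
              }
          if (!mx) continue;
          double ox, oy, val;
          if (!refine2d(c, y, x, ox, oy, val)) continue;
          raw.push_back({(int)o, i, x + ox, y + oy, val});
        }
    }
  }
  return raw;
}

static std::vector<double> surf_descriptor(const Img& im, double x, double y,
                                           double sigma, double angle) {
  const int d = 4;                   // 4x4 cells
  double cell = 5.0 * sigma;         // cell width, 20 sigma window overall
  double ca = std::cos(angle), sa = std::sin(angle);
  std::vector<double> desc(d * d * 4, 0.0);
  double gw = 3.3 * sigma;
  int r = (int)std::lround(0.5 * d * cell * std::sqrt(2.0)) + 1;
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double rx = (ca * dx + sa * dy) / cell + d / 2.0;
      double ry = (-sa * dx + ca * dy) / cell + d / 2.0;
      int bx = (int)std::floor(rx), by = (int)std::floor(ry);
      if (bx < 0 || bx >= d || by < 0 || by >= d) continue;
      int px = xi + dx, py = yi + dy;
      if (px < 1 || px >= im.w - 1 || py < 1 || py >= im.h - 1) continue;
      double gx = 0.5 * (im.at(py, px + 1) - im.at(py, px - 1));
      double gy = 0.5 * (im.at(py + 1, px) - im.at(py - 1, px));
      double rgx = ca * gx + sa * gy;  // gradient in keypoint frame
      double rgy = -sa * gx + ca * gy;
      double wgt = std::exp(-0.5 * (dx * dx + dy * dy) / (gw * gw));
      double* cellp = &desc[(by * d + bx) * 4];
      cellp[0] += wgt * rgx;
      cellp[1] += wgt * rgy;
      cellp[2] += wgt * std::fabs(rgx);
      cellp[3] += wgt * std::fabs(rgy);
    }
  double nrm = 0;
  for (double v : desc) nrm += v * v;
  nrm = std::sqrt(nrm);
  if (nrm > 0)
    for (auto& v : desc) v /= nrm;
  return desc;
}

// [[Rcpp::export]]
List cpp_surf(NumericMatrix img, double hessian_thresh, int max_keypoints) {
  Img base = from_R(img);
  for (auto& v : base.d) v /= 255.0;
  const int spo = 3;
  const double sigma0 = 1.6;
  std::vector<Octave> pyr = build_gauss_pyramid(base, sigma0, spo, spo + 3, 4);
  std::vector<RawKP> raw = detect_doh(pyr, spo, sigma0, hessian_thresh);
  sort_cap(raw, max_keypoints);
  std::vector<KP> kps;
  std::vector<std::vector<double>> descs;
  for (const auto& rk : raw) {
    double s_rel = sigma0 * std::pow(2.0, (double)rk.lev / spo);
    const Img& gim = pyr[rk.oct].g[rk.lev];
    double scale = std::pow(2.0, rk.oct);
    for (double ang : dominant_orientations(gim, rk.x, rk.y, s_rel, 2)) {
      kps.push_back({rk.x * scale, rk.y * scale, s_rel * scale, ang, rk.response});
      descs.push_back(surf_descriptor(gim, rk.x, rk.y, s_rel, ang));
    }
  }
  NumericMatrix dm(descs.size(), 64);
  for (size_t i = 0; i < descs.size(); ++i)
    for (int j = 0; j < 64; ++j) dm(i, j) = descs[i][j];
  return kp_result(kps, dm);
}

// ------------------------------------------------------------------
// AKAZE-style backend: binary grid comparison descriptor (LDB-like, 486
// bits over 2x2 / 3x3 / 4x4 grids of per-cell gradient statistics) on the
// Hessian-determinant scale space
// ------------------------------------------------------------------

static std::vector<uint8_t> mldb_descriptor(const Img& im, double x, double y,
                                            double sigma, double angle) {
  double ps = 10.0 * sigma;  // patch half-width
  double ca = std::cos(angle), sa = std::sin(angle);
  const int grids[3] = {2, 3, 4};
  std::vector<uint8_t> bytes(61, 0);
  int bit = 0;
  auto set_bit = [&](bool b) {
    if (b) bytes[bit >> 3] |= (uint8_t)(1u << (bit & 7));
    ++bit;
  };
  for (int gi = 0; gi < 3; ++gi) {
    int g = grids[gi];
    int nc = g * g;
    std::vector<double> mi(nc, 0), mdx(nc, 0), mdy(nc, 0);
    std::vector<int> cnt(nc, 0);
    const int ns = 4;  // samples per cell axis
    double cw = 2.0 * ps / g;
    for (int cy = 0; cy < g; ++cy)
      for (int cx = 0; cx < g; ++cx)
        for (int sy = 0; sy < ns; ++sy)
          for (int sx = 0; sx < ns; ++sx) {
            double lx = -ps + (cx + (sx + 0.5) / ns) * cw;
            double ly = -ps + (cy + (sy + 0.5) / ns) * cw;
            double wx = x + ca * lx - sa * ly;
            double wy = y + sa * lx + ca * ly;
            int px = (int)std::lround(wx), py = (int)std::lround(wy);
            double gx = 0.5 * (im.atc(py, px + 1) - im.atc(py, px - 1));
            double gy = 0.5 * (im.atc(py + 1, px) - im.atc(py - 1, px));
            int c = cy * g + cx;
            mi[c] += bilinear(im, wx, wy);
            mdx[c] += ca * gx + sa * gy;
            mdy[c] += -sa * gx + ca * gy;
            cnt[c]++;
          }
    for (int c = 0; c < nc; ++c)
      if (cnt[c]) {
        mi[c] /= cnt[c];
        mdx[c] /= cnt[c];
        mdy[c] /= cnt[c];
      }
    // first channel: gradient energy per cell, which is insensitive to the
    // slow illumination differences between sessions
    for (int i = 0; i < nc; ++i)
      for (int j = i + 1; j < nc; ++j) {
        set_bit(std::fabs(mdx[i]) + std::fabs(mdy[i]) >
                std::fabs(mdx[j]) + std::fabs(mdy[j]));
        set_bit(mdx[i] > mdx[j]);
        set_bit(mdy[i] > mdy[j]);
      }
  }
  return bytes;
}

// [[Rcpp::export]]
List cpp_akaze(NumericMatrix img, double hessian_thresh, int max_keypoints) {
  Img base = from_R(img);
  for (auto& v : base.d) v /= 255.0;
  const int spo = 3;
  const double sigma0 = 1.6;
  std::vector<Octave> pyr = build_gauss_pyramid(base, sigma0, spo, spo + 3, 3);
  std::vector<RawKP> raw = detect_doh(pyr, spo, sigma0, hessian_thresh);
  sort_cap(raw, max_keypoints);
  std::vector<KP> kps;
  std::vector<std::vector<uint8_t>> descs;
  for (const auto& rk : raw) {
    double s_rel = sigma0 * std::pow(2.0, (double)rk.lev / spo);
    const Img& gim = pyr[rk.oct].g[rk.lev];
    double scale = std::pow(2.0, rk.oct);
    for (double ang : dominant_orientations(gim, rk.x, rk.y, s_rel, 2)) {
      kps.push_back({rk.x * scale, rk.y * scale, s_rel * scale, ang, rk.response});
      descs.push_back(mldb_descriptor(gim, rk.x, rk.y, s_rel, ang));
    }
  }
  return kp_result(kps, pack_bits(descs, 61));
}

// ------------------------------------------------------------------
// FAST corner detector, shared by the ORB- and BRISK-style backends
// ------------------------------------------------------------------

static const int fast_off[16][2] = {  // (dx, dy), radius-3 Bresenham circle
    {0, -3}, {1, -3}, {2, -2}, {3, -1}, {3, 0}, {3, 1}, {2, 2}, {1, 3},
    {0, 3}, {-1, 3}, {-2, 2}, {-3, 1}, {-3, 0}, {-3, -1}, {-2, -2}, {-1, -3}};

// FAST-9/16 with non-maximum suppression; image on the 0..255 scale
static std::vector<KP> detect_fast(const Img& im, double thresh) {
  Img score(im.h, im.w, 0.0);
  for (int y = 3; y < im.h - 3; ++y)
    for (int x = 3; x < im.w - 3; ++x) {
      double p = im.at(y, x);
      int flags[32];
      for (int i = 0; i < 16; ++i) {
        double v = im.at(y + fast_off[i][1], x + fast_off[i][0]);
        flags[i] = v > p + thresh ? 1 : (v < p - thresh ? -1 : 0);
        flags[i + 16] = flags[i];
      }
      int runb = 0, rund = 0, bestb = 0, bestd = 0;
      for (int i = 0; i < 32; ++i) {
        runb = flags[i] == 1 ? runb + 1 : 0;
        rund = flags[i] == -1 ? rund + 1 : 0;
        bestb = std::max(bestb, runb);
        bestd = std::max(bestd, rund);
      }
      if (bestb >= 9 || bestd >= 9) {
        double s = 0;
        for (int i = 0; i < 16; ++i)
          s += std::fabs(im.at(y + fast_off[i][1], x + fast_off[i][0]) - p);
        score.at(y, x) = s;
      }
    }
  std::vector<KP> out;
  for (int y = 3; y < im.h - 3; ++y)
    for (int x = 3; x < im.w - 3; ++x) {
      double s = score.at(y, x);
      if (s <= 0) continue;
      bool mx = true;
      for (int dy = -1; dy <= 1 && mx; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dy == 0 && dx == 0) continue;
          double n = score.at(y + dy, x + dx);
          if (n > s || (n == s && (dy < 0 || (dy == 0 && dx < 0)))) {
            mx = false;
            break;
          }
        }
      if (mx) {
        double ox = 0, oy = 0, val = s;
        refine2d(score, y, x, ox, oy, val);  // sub-pixel peak of the score map
        out.push_back({x + ox, y + oy, 7.0, 0.0, s});
      }
    }
  return out;
}

// intensity-centroid orientation in a circular patch
static double centroid_angle(const Img& im, double x, double y, int radius) {
  double m10 = 0, m01 = 0;
  int xi = (int)std::lround(x), yi = (int)std::lround(y);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      if (dx * dx + dy * dy > radius * radius) continue;
      double v = im.atc(yi + dy, xi + dx);
      m10 += dx * v;
      m01 += dy * v;
    }
  if (m10 == 0 && m01 == 0) return 0.0;
  return std::atan2(m01, m10);
}

// ------------------------------------------------------------------
// ORB-style backend: multiscale FAST + steered random binary tests
// ------------------------------------------------------------------

struct OrbPattern {
  int pts[256][4];  // ax, ay, bx, by
  OrbPattern() {
    uint64_t s = 0x9E3779B97F4A7C15ull;  // fixed: the pattern is part of the method
    auto nxt = [&]() {
      s ^= s << 13;
      s ^= s >> 7;
      s ^= s << 17;
      return s;
    };
    for (int i = 0; i < 256; ++i)
      for (int j = 0; j < 4; ++j) pts[i][j] = (int)(nxt() % 27) - 13;
  }
};
static const OrbPattern orb_pattern;

// [[Rcpp::export]]
List cpp_orb(NumericMatrix img, int n_features, double fast_thresh) {
  Img base = from_R(img);
  const int nlev = 8;
  const double factor = 1.2;
  std::vector<KP> kps;
  std::vector<std::vector<uint8_t>> descs;
  struct Cand {
    KP kp;
    int lev;
    double xl, yl;
  };
  std::vector<Cand> cands;
  std::vector<Img> levels, blurred;
  for (int l = 0; l < nlev; ++l) {
    double sc = std::pow(factor, l);
    int nh = (int)std::lround(base.h / sc), nw = (int)std::lround(base.w / sc);
    if (nh < 24 || nw < 24) break;
    Img lim = l == 0 ? base : resize_bilinear(base, nh, nw);
    for (KP kp : detect_fast(lim, fast_thresh)) {
      double sx = (double)base.w / lim.w, sy = (double)base.h / lim.h;
      KP up = kp;
      up.x = (kp.x + 0.5) * sx - 0.5;
      up.y = (kp.y + 0.5) * sy - 0.5;
      up.size = 31.0 * sc;
      cands.push_back({up, l, kp.x, kp.y});
    }
    levels.push_back(std::move(lim));
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.kp.response != b.kp.response) return a.kp.response > b.kp.response;
    if (a.lev != b.lev) return a.lev < b.lev;
    if (a.kp.y != b.kp.y) return a.kp.y < b.kp.y;
    return a.kp.x < b.kp.x;
  });
  if ((int)cands.size() > n_features) cands.resize(n_features);
  for (auto& lim : levels) blurred.push_back(gauss_blur(lim, 2.0, 2.0));
  for (const auto& c : cands) {
    const Img& lim = levels[c.lev];
    const Img& bim = blurred[c.lev];
    double ang = centroid_angle(lim, c.xl, c.yl, 15);
    double ca = std::cos(ang), sa = std::sin(ang);
    std::vector<uint8_t> bytes(32, 0);
    for (int i = 0; i < 256; ++i) {
      const int* p = orb_pattern.pts[i];
      double ax = c.xl + ca * p[0] - sa * p[1], ay = c.yl + sa * p[0] + ca * p[1];
      double bx = c.xl + ca * p[2] - sa * p[3], by = c.yl + sa * p[2] + ca * p[3];
      if (bilinear(bim, ax, ay) < bilinear(bim, bx, by))
        bytes[i >> 3] |= (uint8_t)(1u << (i & 7));
    }
    KP kp = c.kp;
    kp.angle = ang;
    kps.push_back(kp);
    descs.push_back(std::move(bytes));
  }
  return kp_result(kps, pack_bits(descs, 32));
}

// ------------------------------------------------------------------
// BRISK-style backend: multiscale FAST + concentric-ring binary pattern
// ------------------------------------------------------------------

struct BriskPattern {
  std::vector<double> px, py, psig;                 // 60 sample points
  std::vector<std::pair<int, int>> short_pairs;     // 512 bits
  std::vector<std::pair<int, int>> long_pairs;      // orientation
  BriskPattern() {
    const double radii[5] = {0.0, 2.9, 4.9, 7.4, 10.8};
    const int counts[5] = {1, 10, 14, 15, 20};
    for (int r = 0; r < 5; ++r)
      for (int i = 0; i < counts[r]; ++i) {
        double a = 2 * PI_ * i / counts[r] + (r % 2 ? PI_ / counts[r] : 0.0);
        px.push_back(radii[r] * std::cos(a));
        py.push_back(radii[r] * std::sin(a));
        psig.push_back(std::max(0.5, 0.4 * radii[r]));
      }
    int n = px.size();
    std::vector<std::pair<double, std::pair<int, int>>> sp;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = std::hypot(px[i] - px[j], py[i] - py[j]);
        if (d < 5.85) sp.push_back({d, {i, j}});
        if (d > 8.2) long_pairs.push_back({i, j});
      }
    std::stable_sort(sp.begin(), sp.end(),
                     [](const auto& a, const auto& b) { return a.first < b.first; });
    for (size_t k = 0; k < sp.size() && k < 512; ++k) short_pairs.push_back(sp[k].second);
  }
};
static const BriskPattern brisk_pattern;

// [[Rcpp::export]]
List cpp_brisk(NumericMatrix img, double fast_thresh, int max_keypoints) {
  Img base = from_R(img);
  const int nlev = 4;
  const double factor = std::sqrt(2.0);
  std::vector<KP> kps;
  std::vector<std::vector<uint8_t>> descs;
  struct Cand {
    KP kp;
    int lev;
    double xl, yl;
  };
  std::vector<Cand> cands;
  std::vector<Img> levels;
  for (int l = 0; l < nlev; ++l) {
    double sc = std::pow(factor, l);
    int nh = (int)std::lround(base.h / sc), nw = (int)std::lround(base.w / sc);
    if (nh < 32 || nw < 32) break;
    Img lim = l == 0 ? base : resize_bilinear(base, nh, nw);
    for (KP kp : detect_fast(lim, fast_thresh)) {
      double sx = (double)base.w / lim.w, sy = (double)base.h / lim.h;
      KP up = kp;
      up.x = (kp.x + 0.5) * sx - 0.5;
      up.y = (kp.y + 0.5) * sy - 0.5;
      up.size = 12.0 * sc;
      cands.push_back({up, l, kp.x, kp.y});
    }
    levels.push_back(std::move(lim));
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.kp.response != b.kp.response) return a.kp.response > b.kp.response;
    if (a.lev != b.lev) return a.lev < b.lev;
    if (a.kp.y != b.kp.y) return a.kp.y < b.kp.y;
    return a.kp.x < b.kp.x;
  });
  if ((int)cands.size() > max_keypoints) cands.resize(max_keypoints);
  // smoothed copies used for the ring samples (sigma grows with ring radius)
  std::vector<std::vector<Img>> smooth(levels.size());
  const double sigs[3] = {0.8, 2.0, 3.6};
  for (size_t l = 0; l < levels.size(); ++l)
    for (double s : sigs) smooth[l].push_back(gauss_blur(levels[l], s, s));
  auto sample = [&](size_t lev, int pt, double cx, double cy, double ca, double sa) {
    double lx = brisk_pattern.px[pt], ly = brisk_pattern.py[pt];
    double wx = cx + ca * lx - sa * ly, wy = cy + sa * lx + ca * ly;
    double sg = brisk_pattern.psig[pt];
    int si = sg < 1.4 ? 0 : (sg < 2.8 ? 1 : 2);
    return bilinear(smooth[lev][si], wx, wy);
  };
  for (const auto& c : cands) {
    // orientation from long-distance pairs (unrotated pattern)
    double gx = 0, gy = 0;
    std::vector<double> vals(brisk_pattern.px.size());
    for (size_t i = 0; i < vals.size(); ++i)
      vals[i] = sample(c.lev, i, c.xl, c.yl, 1.0, 0.0);
    for (const auto& pr : brisk_pattern.long_pairs) {
      double dx = brisk_pattern.px[pr.first] - brisk_pattern.px[pr.second];
      double dy = brisk_pattern.py[pr.first] - brisk_pattern.py[pr.second];
      double d2 = dx * dx + dy * dy;
      double dv = (vals[pr.first] - vals[pr.second]) / d2;
      gx += dv * dx;
      gy += dv * dy;
    }
    double ang = (gx == 0 && gy == 0) ? 0.0 : std::atan2(gy, gx);
    double ca = std::cos(ang), sa = std::sin(ang);
    for (size_t i = 0; i < vals.size(); ++i)
      vals[i] = sample(c.lev, i, c.xl, c.yl, ca, sa);
    std::vector<uint8_t> bytes(64, 0);
    for (size_t b = 0; b < brisk_pattern.short_pairs.size(); ++b) {
      const auto& pr = brisk_pattern.short_pairs[b];
      if (vals[pr.first] > vals[pr.second]) bytes[b >> 3] |= (uint8_t)(1u << (b & 7));
    }
    KP kp = c.kp;
    kp.angle = ang;
    kps.push_back(kp);
    descs.push_back(std::move(bytes));
  }
  return kp_result(kps, pack_bits(descs, 64));
}
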