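#include "common.h"
#include <climits>
#include <unordered_map>
using namespace Rcpp;

// For each row of A, its two nearest rows of B.  Returns nA x 4:
// (best index 1-based, second index 1-based, d1, d2).
// [[Rcpp::export]]
NumericMatrix cpp_nndr_l2(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  // contiguous row-major copies for cache-friendly scanning
  std::vector<double> a((size_t)na * d), b((size_t)nb * d);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < d; ++j) a[(size_t)i * d + j] = A(i, j);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < d; ++j) b[(size_t)i * d + j] = B(i, j);
  NumericMatrix out(na, 4);
  for (int i = 0; i < na; ++i) {
    double d1 = R_PosInf, d2 = R_PosInf;
    int i1 = -1, i2 = -1;
    const double* ar = &a[(size_t)i * d];
    for (int j = 0; j < nb; ++j) {
      const double* br = &b[(size_t)j * d];
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double df = ar[k] - br[k];
        s += df * df;
      }
      if (s < d1) {
        d2 = d1;
        i2 = i1;
        d1 = s;
        i1 = j;
      } else if (s < d2) {
        d2 = s;
        i2 = j;
      }
    }
    out(i, 0) = i1 + 1;
    out(i, 1) = i2 + 1;
    out(i, 2) = std::sqrt(d1);
    out(i, 3) = std::sqrt(d2);
  }
  return out;
}

static inline int popcount8(uint8_t v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(v);
#else
  int c = 0;
  while (v) {
    v &= v - 1;
    ++c;
  }
  return c;
#endif
}

// [[Rcpp::export]]
NumericMatrix cpp_nndr_hamming(RawMatrix A, RawMatrix B) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  std::vector<uint8_t> a((size_t)na * d), b((size_t)nb * d);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < d; ++j) a[(size_t)i * d + j] = A(i, j);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < d; ++j) b[(size_t)i * d + j] = B(i, j);
  NumericMatrix out(na, 4);
  for (int i = 0; i < na; ++i) {
    int d1 = INT_MAX, d2 = INT_MAX, i1 = -1, i2 = -1;
    const uint8_t* ar = &a[(size_t)i * d];
    for (int j = 0; j < nb; ++j) {
      const uint8_t* br = &b[(size_t)j * d];
      int s = 0;
      for (int k = 0; k < d; ++k) s += popcount8((uint8_t)(ar[k] ^ br[k]));
      if (s < d1) {
        d2 = d1;
        i2 = i1;
        d1 = s;
        i1 = j;
      } else if (s < d2) {
        d2 = s;
        i2 = j;
      }
    }
    out(i, 0) = i1 + 1;
    out(i, 1) = i2 + 1;
    out(i, 2) = d1;
    out(i, 3) = d2;
  }
  return out;
}

// xorshift64* PRNG: all RANSAC randomness flows from the caller's seed
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x106689D45497FDB5ull) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1Dull;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// exact affine through 3 point pairs; returns false when degenerate
static bool affine_from3(const double* ax, const double* ay, const double* bx,
                         const double* by, double* T) {
  double d = ax[0] * (ay[1] - ay[2]) - ay[0] * (ax[1] - ax[2]) +
             (ax[1] * ay[2] - ax[2] * ay[1]);
  if (std::fabs(d) < 1e-9) return false;
  // solve [x y 1] * [a c; b d; e f] = [x' y'] by Cramer's rule
  for (int r = 0; r < 2; ++r) {
    const double* t = r == 0 ? bx : by;
    double da = t[0] * (ay[1] - ay[2]) - ay[0] * (t[1] - t[2]) +
                (t[1] * ay[2] - t[2] * ay[1]);
    double db = ax[0] * (t[1] - t[2]) - t[0] * (ax[1] - ax[2]) +
                (ax[1] * t[2] - ax[2] * t[1]);
    double de = ax[0] * (ay[1] * t[2] - ay[2] * t[1]) -
                ay[0] * (ax[1] * t[2] - ax[2] * t[1]) +
                t[0] * (ax[1] * ay[2] - ax[2] * ay[1]);
    T[r * 3 + 0] = da / d;
    T[r * 3 + 1] = db / d;
    T[r * 3 + 2] = de / d;
  }
  return true;
}

// least-squares affine over an index set (normal equations)
static bool affine_lsq(const NumericMatrix& A, const NumericMatrix& B,
                       const std::vector<int>& idx, double* T) {
  double M[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double rx[3] = {0, 0, 0}, ry[3] = {0, 0, 0};
  for (int i : idx) {
    double v[3] = {A(i, 0), A(i, 1), 1.0};
    for (int r = 0; r < 3; ++r) {
      for (int c = 0; c < 3; ++c) M[r][c] += v[r] * v[c];
      rx[r] += v[r] * B(i, 0);
      ry[r] += v[r] * B(i, 1);
    }
  }
  // gaussian elimination with partial pivoting, two right-hand sides
  double aug[3][5];
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) aug[r][c] = M[r][c];
    aug[r][3] = rx[r];
    aug[r][4] = ry[r];
  }
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(aug[r][col]) > std::fabs(aug[piv][col])) piv = r;
    if (std::fabs(aug[piv][col]) < 1e-12) return false;
    if (piv != col)
      for (int c = 0; c < 5; ++c) std::swap(aug[piv][c], aug[col][c]);
    for (int r = 0; r < 3; ++r) {
      if (r == col) continue;
      double f = aug[r][col] / aug[col][col];
      for (int c = col; c < 5; ++c) aug[r][c] -= f * aug[col][c];
    }
  }
  // layout: (a, b, e) then (c, d, f)
  T[0] = aug[0][3] / aug[0][0];
  T[1] = aug[1][3] / aug[1][1];
  T[2] = aug[2][3] / aug[2][2];
  T[3] = aug[0][4] / aug[0][0];
  T[4] = aug[1][4] / aug[1][1];
  T[5] = aug[2][4] / aug[2][2];
  return true;
}

// Robust affine estimation.  ptsA/ptsB are n x 2 matched coordinates.
// Early exit once the adaptive iteration bound for `confidence` is reached.
// [[Rcpp::export]]
List cpp_ransac_affine(NumericMatrix ptsA, NumericMatrix ptsB, int max_iter,
                       double confidence, double thresh, double seed) {
  int n = ptsA.nrow();
  Rng rng((uint64_t)seed);
  double t2 = thresh * thresh;
  int best_n = -1;
  double best_err = R_PosInf;
  double bestT[6];
  long need = max_iter;
  long iter = 0;
  for (; iter < need && iter < (long)max_iter; ++iter) {
    int i0 = rng.below(n), i1 = rng.below(n), i2 = rng.below(n);
    if (i0 == i1 || i0 == i2 || i1 == i2) continue;
    double ax[3] = {ptsA(i0, 0), ptsA(i1, 0), ptsA(i2, 0)};
    double ay[3] = {ptsA(i0, 1), ptsA(i1, 1), ptsA(i2, 1)};
    double bx[3] = {ptsB(i0, 0), ptsB(i1, 0), ptsB(i2, 0)};
    double by[3] = {ptsB(i0, 1), ptsB(i1, 1), ptsB(i2, 1)};
    double T[6];
    if (!affine_from3(ax, ay, bx, by, T)) continue;
    int cnt = 0;
    double err = 0;
    for (int i = 0; i < n; ++i) {
      double px = T[0] * ptsA(i, 0) + T[1] * ptsA(i, 1) + T[2];
      double py = T[3] * ptsA(i, 0) + T[4] * ptsA(i, 1) + T[5];
      double dx = px - ptsB(i, 0), dy = py - ptsB(i, 1);
      double e = dx * dx + dy * dy;
      if (e <= t2) {
        ++cnt;
        err += e;
      }
    }
    if (cnt > best_n || (cnt == best_n && err < best_err)) {
      best_n = cnt;
      best_err = err;
      for (int k = 0; k < 6; ++k) bestT[k] = T[k];
      if (cnt >= 3) {
        double w = (double)cnt / n;
        double p_fail = 1.0 - w * w * w;
        if (p_fail < 1e-12)
          need = iter + 1;
        else {
          double k = std::log(1.0 - confidence) / std::log(p_fail);
          need = (long)std::ceil(std::max(1.0, k));
        }
      }
    }
  }
  if (best_n < 3)
    return List::create(Named("ok") = false, Named("n_iter") = (double)iter);
  // least-squares refit on the consensus set, then final inlier flags
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    double px = bestT[0] * ptsA(i, 0) + bestT[1] * ptsA(i, 1) + bestT[2];
    double py = bestT[3] * ptsA(i, 0) + bestT[4] * ptsA(i, 1) + bestT[5];
    double dx = px - ptsB(i, 0), dy = py - ptsB(i, 1);
    if (dx * dx + dy * dy <= t2) idx.push_back(i);
  }
  double T[6];
  if (!affine_lsq(ptsA, ptsB, idx, T))
    for (int k = 0; k < 6; ++k) T[k] = bestT[k];
  LogicalVector inl(n);
  int n_in = 0;
  for (int i = 0; i < n; ++i) {
    double px = T[0] * ptsA(i, 0) + T[1] * ptsA(i, 1) + T[2];
    double py = T[3] * ptsA(i, 0) + T[4] * ptsA(i, 1) + T[5];
    double dx = px - ptsB(i, 0), dy = py - ptsB(i, 1);
    inl[i] = (dx * dx + dy * dy <= t2);
    if (inl[i]) ++n_in;
  }
  NumericMatrix Tm(2, 3);
  Tm(0, 0) = T[0];
  Tm(0, 1) = T[1];
  Tm(0, 2) = T[2];
  Tm(1, 0) = T[3];
  Tm(1, 1) = T[4];
  Tm(1, 2) = T[5];
  return List::create(Named("ok") = true, Named("transform") = Tm,
                      Named("inliers") = inl, Named("n_inliers") = n_in,
                      Named("n_iter") = (double)iter);
}

// Duplicate suppression for pooled keypoints: among points closer than 1 px
// whose descriptors agree within `tol`, only the first (by input order) is
// kept.  tol = 0 demands bit-identical descriptors; a small positive value
// also collapses the near-duplicates that overlapping simulated views
// produce through resampling.
template <typename Getter>
static LogicalVector dedupe_impl(const NumericMatrix& xy, Getter same) {
  int n = xy.nrow();
  LogicalVector keep(n, true);
  // 1 px grid buckets
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [](int cx, int cy) { return ((long long)cx << 32) ^ (unsigned int)cy; };
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(xy(i, 0)), cy = (int)std::floor(xy(i, 1));
    bool dup = false;
    for (int dy = -1; dy <= 1 && !dup; ++dy)
      for (int dx = -1; dx <= 1 && !dup; ++dx) {
        auto it = grid.find(key(cx + dx, cy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double ddx = xy(i, 0) - xy(j, 0), ddy = xy(i, 1) - xy(j, 1);
          if (ddx * ddx + ddy * ddy < 1.0 && same(i, j)) {
            dup = true;
            break;
          }
        }
      }
    if (dup)
      keep[i] = false;
    else
      grid[key(cx, cy)].push_back(i);
  }
  return keep;
}

// [[Rcpp::export]]
LogicalVector cpp_dedupe_l2(NumericMatrix xy, NumericMatrix desc, double tol) {
  int d = desc.ncol();
  double t2 = tol * tol;
  return dedupe_impl(xy, [&](int i, int j) {
    double s = 0;
    for (int k = 0; k < d; ++k) {
      double df = desc(i, k) - desc(j, k);
      s += df * df;
      if (s > t2) return false;
    }
    return true;
  });
}

// [[Rcpp::export]]
LogicalVector cpp_dedupe_hamming(NumericMatrix xy, RawMatrix desc, int tol) {
  int d = desc.ncol();
  return dedupe_impl(xy, [&](int i, int j) {
    int s = 0;
    for (int k = 0; k < d; ++k) {
      s += popcount8((uint8_t)(desc(i, k) ^ desc(j, k)));
      if (s > tol) return false;
    }
    return true;
  });
}
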