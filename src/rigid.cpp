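#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bilinear lookup with NA outside the image. Matrices are indexed
// [row, col] = [y, x], coordinates are 0-based doubles.
static inline double bilin(const double *img, int H, int W, double x, double y) {
  if (x < 0.0 || y < 0.0 || x > W - 1.0 || y > H - 1.0) return NA_REAL;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  double v00 = img[x0 * H + y0], v10 = img[x1 * H + y0];
  double v01 = img[x0 * H + y1], v11 = img[x1 * H + y1];
  return (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11);
}

// out(x) = img(W(x)),  W(x) = R(theta) (x - c) + c + t,  fill outside with `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_sample_rigid(NumericMatrix img, double tx, double ty,
                               double thetaDeg, double cx, double cy,
                               double fill = 0.0) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double th = thetaDeg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  const double *p = img.begin();
  for (int x = 0; x < W; ++x) {
    double u = x - cx;
    for (int y = 0; y < H; ++y) {
      double v = y - cy;
      double wx = ct * u - st * v + cx + tx;
      double wy = st * u + ct * v + cy + ty;
      double val = bilin(p, H, W, wx, wy);
      out(y, x) = ISNA(val) ? fill : val;
    }
  }
  return out;
}

// Vectorised bilinear sampling at arbitrary coordinates; NA outside.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector xs,
                                  NumericVector ys) {
  int H = img.nrow(), W = img.ncol();
  R_xlen_t n = xs.size();
  NumericVector out(n);
  const double *p = img.begin();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = bilin(p, H, W, xs[i], ys[i]);
  return out;
}

// 2x2 (or f x f) block-mean downsampling; trailing rows/cols that do not
// fill a block are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_block_mean(NumericMatrix img, int f) {
  int H = img.nrow() / f, W = img.ncol() / f;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int dx = 0; dx < f; ++dx)
        for (int dy = 0; dy < f; ++dy) s += img(y * f + dy, x * f + dx);
      out(y, x) = s / (f * f);
    }
  return out;
}

// delta-F/F from raw ROI-mean traces. `traces` is T x n (frames x ROIs).
// Baseline F0 at frame t = mean of the `win` preceding raw values, after
// dropping values above 3x the window median (so transients do not inflate
// the baseline). beta = (F - F0)/F0; 0 while no window or F0 <= floorv.
// [[Rcpp::export]]
NumericMatrix cpp_dff_traces(NumericMatrix traces, int win, double floorv) {
  int T = traces.nrow(), n = traces.ncol();
  NumericMatrix beta(T, n);
  std::vector<double> w, keep;
  w.reserve(win);
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < T; ++t) {
      int lo = std::max(0, t - win);
      int m = t - lo;
      if (m == 0) { beta(t, j) = 0.0; continue; }
      w.assign(&traces(lo, j), &traces(lo, j) + m);
      std::vector<double> sorted(w);
      std::nth_element(sorted.begin(), sorted.begin() + m / 2, sorted.end());
      double med = sorted[m / 2];
      if (m % 2 == 0) {
        double lowmax = *std::max_element(sorted.begin(), sorted.begin() + m / 2);
        med = 0.5 * (med + lowmax);
      }
      double s = 0.0; int k = 0;
      if (med > 0) {
        for (int i = 0; i < m; ++i)
          if (w[i] <= 3.0 * med) { s += w[i]; ++k; }
      }
      if (k == 0) { for (int i = 0; i < m; ++i) s += w[i]; k = m; }
      double f0 = s / k;
      // floored denominator: keeps onset transients after dark periods
      beta(t, j) = (traces(t, j) - f0) / std::max(f0, floorv);
    }
  }
  return beta;
}

// Mean over a fixed pixel set for every column of a (npix x T) frame matrix.
// idx is 1-based into the pixel dimension.
// [[Rcpp::export]]
NumericVector cpp_roi_trace(NumericMatrix frames, IntegerVector idx) {
  int T = frames.ncol();
  R_xlen_t m = idx.size();
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    const double *col = &frames(0, t);
    double s = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) s += col[idx[i] - 1];
    out[t] = s / m;
  }
  return out;
}

// Square-window median filter (window side 2r+1), replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int r) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int side = 2 * r + 1, m = side * side;
  std::vector<double> buf(m);
  const double *pi = img.begin();
  double *po = out.begin();
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int k = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = x + dx;
        if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
        const double *col = pi + (size_t)xx * H;
        for (int dy = -r; dy <= r; ++dy) {
          int yy = y + dy;
          if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
          buf[k++] = col[yy];
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      po[(size_t)x * H + y] = buf[m / 2];
    }
  return out;
}

// Convex-hull area (shoelace) of a point set via Andrew monotone chain.
static double hullArea(std::vector<std::pair<int,int>> &p) {
  size_t n = p.size();
  if (n < 3) return 0.0;
  std::sort(p.begin(), p.end());
  std::vector<std::pair<int,int>> h(2 * n);
  auto cross = [](const std::pair<int,int> &o, const std::pair<int,int> &a,
                  const std::pair<int,int> &b) {
    return (double)(a.first - o.first) * (b.second - o.second) -
           (double)(a.second - o.second) * (b.first - o.first);
  };
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2 && cross(h[k - 2], h[k - 1], p[i]) <= 0) --k;
    h[k++] = p[i];
  }
  for (size_t i = n - 1, t = k + 1; i > 0; --i) {
    while (k >= t && cross(h[k - 2], h[k - 1], p[i - 1]) <= 0) --k;
    h[k++] = p[i - 1];
  }
  h.resize(k - 1);
  double area2 = 0.0;
  size_t m = h.size();
  for (size_t i = 0; i < m; ++i) {
    size_t j = (i + 1) % m;
    area2 += (double)h[i].first * h[j].second -
             (double)h[j].first * h[i].second;
  }
  // digital hull pixel count ~ shoelace + boundary/2 + 1 (Pick)
  return std::fabs(area2) / 2.0 + m / 2.0 + 1.0;
}

// Connected components (4-connectivity) above an intensity threshold,
// with per-component statistics. stats has one row per component with
// area in [aMin, aMax]; columns are
// area, cx, cy, radius, mu20, mu02, mu11, boundary, hullPix, label,
// where label indexes the returned full label image.
// [[Rcpp::export]]
List cpp_blob_level(NumericMatrix frame, double level,
                    double aMin, double aMax) {
  int H = frame.nrow(), W = frame.ncol();
  std::vector<int> lab(H * W, 0);
  const double *p = frame.begin();
  int nlab = 0;
  std::vector<int> stack;
  std::vector<long> areas;
  for (int i = 0; i < H * W; ++i) {
    if (lab[i] != 0 || !(p[i] > level)) continue;
    ++nlab;
    long area = 0;
    stack.push_back(i);
    lab[i] = nlab;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      ++area;
      int y = j % H, x = j / H;
      const int nb[4] = {j - 1, j + 1, j - H, j + H};
      const bool okb[4] = {y > 0, y < H - 1, x > 0, x < W - 1};
      for (int k = 0; k < 4; ++k) {
        if (okb[k] && lab[nb[k]] == 0 && p[nb[k]] > level) {
          lab[nb[k]] = nlab;
          stack.push_back(nb[k]);
        }
      }
    }
    areas.push_back(area);
  }
  // components in area range
  std::vector<int> id(nlab + 1, 0);
  int nkeep = 0;
  for (int l = 1; l <= nlab; ++l) {
    if (areas[l - 1] >= aMin && areas[l - 1] <= aMax) id[l] = ++nkeep;
  }
  IntegerMatrix labmat(H, W);
  std::copy(lab.begin(), lab.end(), labmat.begin());
  NumericMatrix out(nkeep, 10);
  if (nkeep == 0) return List::create(_["stats"] = out,
                                      _["labels"] = labmat);
  std::vector<double> A(nkeep, 0), SX(nkeep, 0), SY(nkeep, 0),
      R2(nkeep, 0), M20(nkeep, 0), M02(nkeep, 0), M11(nkeep, 0),
      B(nkeep, 0);
  std::vector<std::vector<std::pair<int,int>>> pts(nkeep);
  // first pass: sums for centroids
  for (int i = 0; i < H * W; ++i) {
    int g = lab[i] ? id[lab[i]] : 0;
    if (!g) continue;
    A[g - 1] += 1;
    SX[g - 1] += i / H;
    SY[g - 1] += i % H;
  }
  for (int g = 0; g < nkeep; ++g) { SX[g] /= A[g]; SY[g] /= A[g]; }
  // second pass: radius, central moments, boundary count
  for (int i = 0; i < H * W; ++i) {
    int g = lab[i] ? id[lab[i]] : 0;
    if (!g) continue;
    int y = i % H, x = i / H;
    double dx = x - SX[g - 1], dy = y - SY[g - 1];
    double d2 = dx * dx + dy * dy;
    if (d2 > R2[g - 1]) R2[g - 1] = d2;
    M20[g - 1] += dx * dx;
    M02[g - 1] += dy * dy;
    M11[g - 1] += dx * dy;
    pts[g - 1].push_back(std::make_pair(x, y));
    bool boundary =
      (y == 0 || !(p[i - 1] > level)) || (y == H - 1 || !(p[i + 1] > level)) ||
      (x == 0 || !(p[i - H] > level)) || (x == W - 1 || !(p[i + H] > level));
    if (boundary) B[g - 1] += 1;
  }
  for (int g = 0; g < nkeep; ++g) {
    out(g, 0) = A[g];
    out(g, 1) = SX[g];
    out(g, 2) = SY[g];
    out(g, 3) = std::sqrt(R2[g]);
    out(g, 4) = M20[g] / A[g];
    out(g, 5) = M02[g] / A[g];
    out(g, 6) = M11[g] / A[g];
    out(g, 7) = B[g];
    out(g, 8) = hullArea(pts[g]);
  }
  // label ids (into the full label image) for pixel retrieval
  for (int l = 1; l <= nlab; ++l) if (id[l]) out(id[l] - 1, 9) = l;
  return List::create(_["stats"] = out, _["labels"] = labmat);
}

// Separable convolution with a symmetric 1-D kernel, replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_sep_filter(NumericMatrix img, NumericVector kernel) {
  int H = img.nrow(), W = img.ncol();
  int r = (kernel.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  const double *pi = img.begin(), *pk = kernel.begin();
  double *pt = tmp.begin(), *po = out.begin();
  for (int x = 0; x < W; ++x) {        // vertical pass
    const double *col = pi + (size_t)x * H;
    double *tcol = pt + (size_t)x * H;
    for (int y = 0; y < H; ++y) {
      double s = 0;
      for (int k = -r; k <= r; ++k) {
        int yy = y + k;
        if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
        s += col[yy] * pk[k + r];
      }
      tcol[y] = s;
    }
  }
  for (int x = 0; x < W; ++x) {        // horizontal pass, column-sequential
    double *ocol = po + (size_t)x * H;
    for (int k = -r; k <= r; ++k) {
      int xx = x + k;
      if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
      const double *tcol = pt + (size_t)xx * H;
      double kv = pk[k + r];
      for (int y = 0; y < H; ++y) ocol[y] += tcol[y] * kv;
    }
  }
  return out;
}
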