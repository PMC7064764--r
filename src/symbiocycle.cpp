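// Compiled kernels for SymbioCycle: 3D labelling, anisotropic Euclidean
// distance transform, h-maxima marker-based watershed, separable Gaussian
// blur and box opening, blob/sphere rendering, hard-core point placement,
// axis-aligned box union volume, kNN, and an incremental 3D convex hull.
//
// All voxel grids are passed as flat vectors in R array order
// (x fastest: idx = x + nx*(y + ny*z)), dims = c(nx, ny, nz),
// spacing = voxel pitch in micrometres per axis.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double BIGF = 1e30;

// ---------------------------------------------------------------------------
// connected components, 26-connectivity
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        R_xlen_t q = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// exact anisotropic squared EDT (Felzenszwalb & Huttenlocher), returns
// distance in micrometres from each foreground voxel to nearest background
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIGF : 0.0;

  std::vector<double> f, d;
  // along x
  f.resize(nx); d.resize(nx);
  double wx = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
    for (int x = 0; x < nx; ++x) f[x] = g[base + x];
    dt1d(f, d, nx, wx);
    for (int x = 0; x < nx; ++x) g[base + x] = d[x];
  }
  // along y
  f.resize(ny); d.resize(ny);
  double wy = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
    dt1d(f, d, ny, wy);
    for (int y = 0; y < ny; ++y) g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
  }
  // along z
  f.resize(nz); d.resize(nz);
  double wz = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) f[z] = g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
    dt1d(f, d, nz, wz);
    for (int z = 0; z < nz; ++z) g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
  }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIGF) ? BIGF : std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// grayscale reconstruction by dilation (Vincent hybrid), 26-connectivity;
// marker <= image assumed
// ---------------------------------------------------------------------------

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_grayrec(NumericVector marker, NumericVector image,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J = clone(marker);

  // forward raster
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    R_xlen_t p = vidx(x, y, z, nx, ny);
    double m = J[p];
    for (int dz = -1; dz <= 0; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      double v = J[vidx(X, Y, Z, nx, ny)];
      if (v > m) m = v;
    }
    J[p] = std::min(m, image[p]);
  }
  // backward raster + queue seeding
  std::queue<R_xlen_t> fifo;
  for (int z = nz - 1; z >= 0; --z) for (int y = ny - 1; y >= 0; --y)
  for (int x = nx - 1; x >= 0; --x) {
    R_xlen_t p = vidx(x, y, z, nx, ny);
    double m = J[p];
    for (int dz = 0; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      double v = J[vidx(X, Y, Z, nx, ny)];
      if (v > m) m = v;
    }
    J[p] = std::min(m, image[p]);
    // seed: any anti-raster neighbour that could still grow
    for (int dz = 0; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t q = vidx(X, Y, Z, nx, ny);
      if (J[q] < J[p] && J[q] < image[q]) { fifo.push(p); goto seeded; }
    }
    seeded: ;
  }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t q = vidx(X, Y, Z, nx, ny);
      if (J[q] < J[p] && image[q] != J[q]) {
        double v = std::min(J[p], image[q]);
        if (v > J[q]) { J[q] = v; fifo.push(q); }
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// regional maxima of an image restricted to mask -> labelled markers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_regmax_markers(NumericVector img, LogicalVector mask,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cand(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) cand[i] = mask[i] ? 1 : 0;
  std::queue<R_xlen_t> fifo;
  // voxels with a strictly greater neighbour are not maxima
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!cand[p]) continue;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1 && cand[p]; ++dz)
    for (int dy = -1; dy <= 1 && cand[p]; ++dy)
    for (int dx = -1; dx <= 1 && cand[p]; ++dx) {
      if (!dx && !dy && !dz) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      if (img[vidx(X, Y, Z, nx, ny)] > img[p]) { cand[p] = 0; fifo.push(p); }
    }
  }
  // propagate removal across equal-valued plateaus
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t q = vidx(X, Y, Z, nx, ny);
      if (cand[q] && img[q] == img[p]) { cand[q] = 0; fifo.push(q); }
    }
  }
  LogicalVector mm(n);
  for (R_xlen_t i = 0; i < n; ++i) mm[i] = cand[i] != 0;
  return cpp_label3d(mm, dims);
}

// ---------------------------------------------------------------------------
// ensure every region label owns at least one marker (at its EDT argmax)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_ensure_markers(IntegerVector markers, IntegerVector regions,
                                 NumericVector edt) {
  const R_xlen_t n = markers.size();
  int maxreg = 0, maxmark = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (regions[i] > maxreg) maxreg = regions[i];
    if (markers[i] > maxmark) maxmark = markers[i];
  }
  std::vector<char> has(maxreg + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && regions[i] > 0) has[regions[i]] = 1;
  std::vector<R_xlen_t> best(maxreg + 1, -1);
  std::vector<double> bestv(maxreg + 1, -1.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int r = regions[i];
    if (r > 0 && !has[r] && edt[i] > bestv[r]) { bestv[r] = edt[i]; best[r] = i; }
  }
  IntegerVector out = clone(markers);
  int next = maxmark;
  for (int r = 1; r <= maxreg; ++r)
    if (!has[r] && best[r] >= 0) out[best[r]] = ++next;
  return out;
}

// ---------------------------------------------------------------------------
// marker-based watershed by priority flooding on a height image (descending),
// confined within region labels (never crosses or merges regions)
// ---------------------------------------------------------------------------

struct PQItem {
  double v; long long ord; R_xlen_t idx;
};
struct PQCmp {
  bool operator()(const PQItem& a, const PQItem& b) const {
    if (a.v != b.v) return a.v < b.v;   // max-heap on value
    return a.ord > b.ord;               // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector markers,
                            IntegerVector regions, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  long long ord = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (markers[i] > 0 && regions[i] > 0) {
      out[i] = markers[i];
      pq.push({height[i], ord++, i});
    }
  while (!pq.empty()) {
    PQItem it = pq.top(); pq.pop();
    R_xlen_t p = it.idx;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (!dx && !dy && !dz) continue;
      int X = x + dx, Y = y + dy, Z = z + dz;
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t q = vidx(X, Y, Z, nx, ny);
      if (regions[q] == regions[p] && regions[q] > 0 && out[q] == 0) {
        out[q] = out[p];
        pq.push({height[q], ord++, q});
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian blur, reflect boundary; sigma in voxels per axis
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& img, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), outl(len);
  int n0 = axis == 0 ? ny : nx;
  int n1 = axis == 2 ? ny : nz;
  for (int b = 0; b < n1; ++b) for (int a = 0; a < n0; ++a) {
    for (int i = 0; i < len; ++i) {
      R_xlen_t p;
      if (axis == 0)      p = vidx(i, a, b, nx, ny);
      else if (axis == 1) p = vidx(a, i, b, nx, ny);
      else                p = vidx(a, b, i, nx, ny);
      line[i] = img[p];
    }
    for (int i = 0; i < len; ++i) {
      double acc = 0;
      for (int j = -r; j <= r; ++j) {
        int t = i + j;
        if (t < 0) t = -t - 1;
        if (t >= len) t = 2 * len - t - 1;
        if (t < 0) t = 0; if (t >= len) t = len - 1;
        acc += k[j + r] * line[t];
      }
      outl[i] = acc;
    }
    for (int i = 0; i < len; ++i) {
      R_xlen_t p;
      if (axis == 0)      p = vidx(i, a, b, nx, ny);
      else if (axis == 1) p = vidx(a, i, b, nx, ny);
      else                p = vidx(a, b, i, nx, ny);
      img[p] = outl[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dims,
                          NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> w(img.begin(), img.end());
  blur_axis(w, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(w, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(w, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(w.begin(), w.end());
}

// ---------------------------------------------------------------------------
// separable grayscale box opening (erosion then dilation); radii in voxels
// ---------------------------------------------------------------------------

static void minmax_axis(std::vector<double>& img, int nx, int ny, int nz,
                        int axis, int r, bool takeMin) {
  if (r <= 0) return;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), outl(len);
  int n0 = axis == 0 ? ny : nx;
  int n1 = axis == 2 ? ny : nz;
  for (int b = 0; b < n1; ++b) for (int a = 0; a < n0; ++a) {
    for (int i = 0; i < len; ++i) {
      R_xlen_t p;
      if (axis == 0)      p = vidx(i, a, b, nx, ny);
      else if (axis == 1) p = vidx(a, i, b, nx, ny);
      else                p = vidx(a, b, i, nx, ny);
      line[i] = img[p];
    }
    for (int i = 0; i < len; ++i) {
      int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
      double m = line[lo];
      for (int t = lo + 1; t <= hi; ++t)
        m = takeMin ? std::min(m, line[t]) : std::max(m, line[t]);
      outl[i] = m;
    }
    for (int i = 0; i < len; ++i) {
      R_xlen_t p;
      if (axis == 0)      p = vidx(i, a, b, nx, ny);
      else if (axis == 1) p = vidx(a, i, b, nx, ny);
      else                p = vidx(a, b, i, nx, ny);
      img[p] = outl[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_boxopen(NumericVector img, IntegerVector dims,
                          IntegerVector rad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> w(img.begin(), img.end());
  for (int ax = 0; ax < 3; ++ax) minmax_axis(w, nx, ny, nz, ax, rad[ax], true);
  for (int ax = 0; ax < 3; ++ax) minmax_axis(w, nx, ny, nz, ax, rad[ax], false);
  return NumericVector(w.begin(), w.end());
}

// ---------------------------------------------------------------------------
// rendering: Gaussian blobs and solid spheres on an anisotropic grid;
// voxel centre of voxel (i,j,k) (0-based) is at ((i+.5)dx,(j+.5)dy,(k+.5)dz)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_render_gauss(IntegerVector dims, NumericVector spacing,
                               NumericMatrix pts, double sigma_um,
                               double amplitude) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector img((R_xlen_t)nx * ny * nz, 0.0);
  const double cut = 3.5 * sigma_um;
  for (int p = 0; p < pts.nrow(); ++p) {
    double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    int x0 = std::max(0, (int)std::floor((cx - cut) / spacing[0] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + cut) / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - cut) / spacing[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + cut) / spacing[1] - 0.5));
    int z0 = std::max(0, (int)std::floor((cz - cut) / spacing[2] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + cut) / spacing[2] - 0.5));
    for (int z = z0; z <= z1; ++z) {
      double ddz = (z + 0.5) * spacing[2] - cz;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (y + 0.5) * spacing[1] - cy;
        for (int x = x0; x <= x1; ++x) {
          double ddx = (x + 0.5) * spacing[0] - cx;
          double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          img[vidx(x, y, z, nx, ny)] +=
            amplitude * std::exp(-0.5 * r2 / (sigma_um * sigma_um));
        }
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericVector cpp_render_spheres(IntegerVector dims, NumericVector spacing,
                                 NumericMatrix centers, NumericVector radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector img((R_xlen_t)nx * ny * nz, 0.0);
  for (int p = 0; p < centers.nrow(); ++p) {
    double r = radius.size() == 1 ? radius[0] : radius[p];
    double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    int x0 = std::max(0, (int)std::floor((cx - r) / spacing[0] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + r) / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - r) / spacing[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + r) / spacing[1] - 0.5));
    int z0 = std::max(0, (int)std::floor((cz - r) / spacing[2] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r) / spacing[2] - 0.5));
    double r2 = r * r;
    for (int z = z0; z <= z1; ++z) {
      double ddz = (z + 0.5) * spacing[2] - cz;
      for (int y = y0; y <= y1; ++y) {
        double ddy = (y + 0.5) * spacing[1] - cy;
        for (int x = x0; x <= x1; ++x) {
          double ddx = (x + 0.5) * spacing[0] - cx;
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r2)
            img[vidx(x, y, z, nx, ny)] = 1.0;
        }
      }
    }
  }
  return img;
}

// ---------------------------------------------------------------------------
// per-label statistics: voxel count, intensity-weighted centre of mass (um),
// voxel bounding box (1-based inclusive indices)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_com_stats(IntegerVector labels, NumericVector intensity,
                            IntegerVector dims, NumericVector spacing,
                            int nlab) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nlab, 11);
  // cols: count, wsum, sx, sy, sz (weighted), ix0,ix1,iy0,iy1,iz0,iz1
  for (int l = 0; l < nlab; ++l) {
    out(l, 5) = nx + 1; out(l, 6) = 0;
    out(l, 7) = ny + 1; out(l, 8) = 0;
    out(l, 9) = nz + 1; out(l, 10) = 0;
  }
  for (R_xlen_t p = 0; p < n; ++p) {
    int l = labels[p];
    if (l <= 0 || l > nlab) continue;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    double w = intensity.size() ? intensity[p] : 1.0;
    if (w < 0) w = 0;
    int r = l - 1;
    out(r, 0) += 1;
    out(r, 1) += w;
    out(r, 2) += w * (x + 0.5) * spacing[0];
    out(r, 3) += w * (y + 0.5) * spacing[1];
    out(r, 4) += w * (z + 0.5) * spacing[2];
    if (x + 1 < out(r, 5)) out(r, 5) = x + 1;
    if (x + 1 > out(r, 6)) out(r, 6) = x + 1;
    if (y + 1 < out(r, 7)) out(r, 7) = y + 1;
    if (y + 1 > out(r, 8)) out(r, 8) = y + 1;
    if (z + 1 < out(r, 9)) out(r, 9) = z + 1;
    if (z + 1 > out(r, 10)) out(r, 10) = z + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// hard-core point placement (uses the R RNG, so set.seed() governs it)
// ---------------------------------------------------------------------------

struct CellGrid {
  // uniform cells of size >= rmin per axis; optional periodic wrap so that
  // placement is translation-invariant on the torus (exactly uniform
  // one-point marginal)
  double lo[3], len[3], csz[3];
  int gd[3];
  bool periodic;
  std::vector<std::vector<int>> cells;
  CellGrid(const double* lo_, const double* hi_, double rmin, bool per) {
    periodic = per;
    double cell = rmin > 0 ? rmin : 1.0;
    for (int a = 0; a < 3; ++a) {
      lo[a] = lo_[a];
      len[a] = hi_[a] - lo_[a];
      gd[a] = std::max(1, (int)std::floor(len[a] / cell));
      csz[a] = len[a] / gd[a];
    }
    cells.resize((size_t)gd[0] * gd[1] * gd[2]);
  }
  void cellOf(const double* p, int* c) const {
    for (int a = 0; a < 3; ++a) {
      c[a] = (int)((p[a] - lo[a]) / csz[a]);
      if (c[a] < 0) c[a] = 0;
      if (c[a] >= gd[a]) c[a] = gd[a] - 1;
    }
  }
  double dist2(const double* p, const double* q) const {
    double s = 0;
    for (int a = 0; a < 3; ++a) {
      double d = std::fabs(p[a] - q[a]);
      if (periodic && len[a] - d < d) d = len[a] - d;
      s += d * d;
    }
    return s;
  }
  bool ok(const double* p, const std::vector<double>& xs, double rmin) const {
    if (rmin <= 0) return true;
    int c[3];
    cellOf(p, c);
    double r2 = rmin * rmin;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      int X = c[0] + dx, Y = c[1] + dy, Z = c[2] + dz;
      if (periodic) {
        X = (X + gd[0]) % gd[0];
        Y = (Y + gd[1]) % gd[1];
        Z = (Z + gd[2]) % gd[2];
      } else if (X < 0 || Y < 0 || Z < 0 || X >= gd[0] || Y >= gd[1] || Z >= gd[2])
        continue;
      const std::vector<int>& cl = cells[(size_t)X + (size_t)gd[0] * (Y + (size_t)gd[1] * Z)];
      for (int id : cl)
        if (dist2(p, &xs[3 * id]) < r2) return false;
    }
    return true;
  }
  void add(const double* p, int id, std::vector<double>& xs) {
    xs.push_back(p[0]); xs.push_back(p[1]); xs.push_back(p[2]);
    int c[3];
    cellOf(p, c);
    cells[(size_t)c[0] + (size_t)gd[0] * (c[1] + (size_t)gd[1] * c[2])].push_back(id);
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_hardcore_uniform(int n, NumericVector lo, NumericVector hi,
                                   double rmin, int max_tries,
                                   std::string what, bool periodic = true) {
  RNGScope scope;
  double L[3] = {lo[0], lo[1], lo[2]}, H[3] = {hi[0], hi[1], hi[2]};
  CellGrid grid(L, H, rmin, periodic);
  std::vector<double> xs;
  xs.reserve(3 * n);
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      double p[3];
      for (int a = 0; a < 3; ++a) p[a] = L[a] + unif_rand() * (H[a] - L[a]);
      if (grid.ok(p, xs, rmin)) { grid.add(p, i, xs); placed = true; break; }
    }
    if (!placed)
      stop("hard-core placement failed for %s at point %d of %d: density too high for the minimum separation %.2f um",
           what.c_str(), i + 1, n, rmin);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = xs[3 * i + a];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_thomas_hardcore(int n, NumericMatrix parents, double sigma,
                                  NumericVector lo, NumericVector hi,
                                  double rmin, int max_tries,
                                  std::string what) {
  RNGScope scope;
  double L[3] = {lo[0], lo[1], lo[2]}, H[3] = {hi[0], hi[1], hi[2]};
  CellGrid grid(L, H, rmin, false);
  std::vector<double> xs;
  xs.reserve(3 * n);
  int np = parents.nrow();
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      int k = std::min(np - 1, (int)(unif_rand() * np));
      double p[3];
      bool inside = true;
      for (int a = 0; a < 3; ++a) {
        p[a] = parents(k, a) + norm_rand() * sigma;
        if (p[a] < L[a] || p[a] > H[a]) { inside = false; break; }
      }
      if (!inside) continue;
      if (grid.ok(p, xs, rmin)) { grid.add(p, i, xs); placed = true; break; }
    }
    if (!placed)
      stop("clustered hard-core placement failed for %s at point %d of %d: symbiont_count too high for cluster_sigma_um/minimum separation %.2f um",
           what.c_str(), i + 1, n, rmin);
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = xs[3 * i + a];
  return out;
}

// ---------------------------------------------------------------------------
// distances and box membership
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix pts, NumericMatrix ref) {
  NumericVector out(pts.nrow());
  if (ref.nrow() == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  for (int i = 0; i < pts.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < ref.nrow(); ++j) {
      double d0 = pts(i, 0) - ref(j, 0), d1 = pts(i, 1) - ref(j, 1),
             d2 = pts(i, 2) - ref(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_in_any_box(NumericMatrix pts, NumericMatrix boxes) {
  // boxes cols: xmin xmax ymin ymax zmin zmax; closed intervals
  LogicalVector out(pts.nrow(), false);
  for (int i = 0; i < pts.nrow(); ++i) {
    for (int b = 0; b < boxes.nrow(); ++b) {
      if (pts(i, 0) >= boxes(b, 0) && pts(i, 0) <= boxes(b, 1) &&
          pts(i, 1) >= boxes(b, 2) && pts(i, 1) <= boxes(b, 3) &&
          pts(i, 2) >= boxes(b, 4) && pts(i, 2) <= boxes(b, 5)) {
        out[i] = true; break;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_union_volume(NumericMatrix boxes) {
  const int n = boxes.nrow();
  if (n == 0) return 0.0;
  std::vector<double> xs;
  xs.reserve(2 * n);
  for (int i = 0; i < n; ++i) { xs.push_back(boxes(i, 0)); xs.push_back(boxes(i, 1)); }
  std::sort(xs.begin(), xs.end());
  xs.erase(std::unique(xs.begin(), xs.end()), xs.end());
  double total = 0.0;
  std::vector<int> act;
  std::vector<double> ys;
  std::vector<std::pair<double, double>> zint;
  for (size_t s = 0; s + 1 < xs.size(); ++s) {
    double x0 = xs[s], x1 = xs[s + 1], w = x1 - x0;
    if (w <= 0) continue;
    act.clear();
    for (int i = 0; i < n; ++i)
      if (boxes(i, 0) <= x0 && boxes(i, 1) >= x1) act.push_back(i);
    if (act.empty()) continue;
    ys.clear();
    for (int i : act) { ys.push_back(boxes(i, 2)); ys.push_back(boxes(i, 3)); }
    std::sort(ys.begin(), ys.end());
    ys.erase(std::unique(ys.begin(), ys.end()), ys.end());
    double area = 0.0;
    for (size_t t = 0; t + 1 < ys.size(); ++t) {
      double y0 = ys[t], y1 = ys[t + 1], h = y1 - y0;
      if (h <= 0) continue;
      zint.clear();
      for (int i : act)
        if (boxes(i, 2) <= y0 && boxes(i, 3) >= y1)
          zint.push_back({boxes(i, 4), boxes(i, 5)});
      if (zint.empty()) continue;
      std::sort(zint.begin(), zint.end());
      double zlen = 0.0, curlo = zint[0].first, curhi = zint[0].second;
      for (size_t q = 1; q < zint.size(); ++q) {
        if (zint[q].first > curhi) {
          zlen += curhi - curlo;
          curlo = zint[q].first; curhi = zint[q].second;
        } else if (zint[q].second > curhi) curhi = zint[q].second;
      }
      zlen += curhi - curlo;
      area += h * zlen;
    }
    total += w * area;
  }
  return total;
}

// ---------------------------------------------------------------------------
// brute-force kNN with partial selection; distances sorted ascending
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_knn(NumericMatrix source, NumericMatrix target, int k,
                      bool exclude_self) {
  const int n = source.nrow(), m = target.nrow();
  NumericMatrix out(n, k);
  std::vector<double> d;
  for (int i = 0; i < n; ++i) {
    d.clear();
    d.reserve(m);
    for (int j = 0; j < m; ++j) {
      if (exclude_self && j == i) continue;
      double d0 = source(i, 0) - target(j, 0), d1 = source(i, 1) - target(j, 1),
             d2 = source(i, 2) - target(j, 2);
      d.push_back(d0 * d0 + d1 * d1 + d2 * d2);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// incremental 3D convex hull; returns volume, surface area and the Steiner
// edge term sum(edge_length * exterior_dihedral_angle)
// ---------------------------------------------------------------------------

struct HFace { int a, b, c; double nx, ny, nz, off; bool alive; };

static void face_plane(const NumericMatrix& P, HFace& f) {
  double ux = P(f.b, 0) - P(f.a, 0), uy = P(f.b, 1) - P(f.a, 1), uz = P(f.b, 2) - P(f.a, 2);
  double vx = P(f.c, 0) - P(f.a, 0), vy = P(f.c, 1) - P(f.a, 1), vz = P(f.c, 2) - P(f.a, 2);
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * P(f.a, 0) + f.ny * P(f.a, 1) + f.nz * P(f.a, 2);
}

// [[Rcpp::export]]
List cpp_convhull3(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  double mins[3] = {R_PosInf, R_PosInf, R_PosInf}, maxs[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) for (int a = 0; a < 3; ++a) {
    mins[a] = std::min(mins[a], P(i, a));
    maxs[a] = std::max(maxs[a], P(i, a));
  }
  double scale = std::max({maxs[0] - mins[0], maxs[1] - mins[1], maxs[2] - mins[2], 1e-12});
  double eps = 1e-9 * scale * scale;        // tolerance on plane offsets (scale^2 from unnormalised normals)

  // initial tetrahedron
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    double d0 = P(i, 0) - P(i0, 0), d1 = P(i, 1) - P(i0, 1), d2 = P(i, 2) - P(i0, 2);
    double d = d0 * d0 + d1 * d1 + d2 * d2;
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 0) stop("all points coincide; hull undefined");
  best = -1;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = P(i1, 0) - P(i0, 0), uy = P(i1, 1) - P(i0, 1), uz = P(i1, 2) - P(i0, 2);
    double vx = P(i, 0) - P(i0, 0), vy = P(i, 1) - P(i0, 1), vz = P(i, 2) - P(i0, 2);
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (best <= 1e-18 * scale * scale * scale * scale)
    stop("points are collinear; hull volume undefined");
  HFace f0 = {i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(P, f0);
  best = -1;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(f0.nx * P(i, 0) + f0.ny * P(i, 1) + f0.nz * P(i, 2) - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("points are coplanar; hull volume undefined (need >=4 non-coplanar nuclei)");

  std::vector<HFace> faces;
  int tet[4] = {i0, i1, i2, i3};
  int fi[4][3] = {{0, 1, 2}, {0, 3, 1}, {0, 2, 3}, {1, 3, 2}};
  for (int f = 0; f < 4; ++f) {
    HFace F = {tet[fi[f][0]], tet[fi[f][1]], tet[fi[f][2]], 0, 0, 0, 0, true};
    face_plane(P, F);
    int other = tet[0] + tet[1] + tet[2] + tet[3] - F.a - F.b - F.c;
    double d = F.nx * P(other, 0) + F.ny * P(other, 1) + F.nz * P(other, 2) - F.off;
    if (d > 0) { std::swap(F.b, F.c); face_plane(P, F); }
    faces.push_back(F);
  }

  std::vector<int> visible;
  std::unordered_set<long long> horizon;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nx * P(i, 0) + faces[f].ny * P(i, 1) + faces[f].nz * P(i, 2) - faces[f].off;
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    horizon.clear();
    auto enc = [](int u, int v) { return (long long)u * 1000003LL + v; };
    for (int f : visible) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (auto& ed : e) {
        long long rev = enc(ed[1], ed[0]);
        if (horizon.count(rev)) horizon.erase(rev);
        else horizon.insert(enc(ed[0], ed[1]));
      }
    }
    for (int f : visible) faces[f].alive = false;
    for (long long code : horizon) {
      int u = (int)(code / 1000003LL), v = (int)(code % 1000003LL);
      HFace F = {u, v, i, 0, 0, 0, 0, true};
      face_plane(P, F);
      faces.push_back(F);
    }
  }

  // volume, area, edge term over alive faces
  double vol = 0, area = 0, edgeTerm = 0;
  std::vector<int> af;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) af.push_back((int)f);
  for (int f : af) {
    const HFace& F = faces[f];
    vol += (P(F.a, 0) * (P(F.b, 1) * P(F.c, 2) - P(F.b, 2) * P(F.c, 1)) -
            P(F.a, 1) * (P(F.b, 0) * P(F.c, 2) - P(F.b, 2) * P(F.c, 0)) +
            P(F.a, 2) * (P(F.b, 0) * P(F.c, 1) - P(F.b, 1) * P(F.c, 0))) / 6.0;
    area += 0.5 * std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
  }
  // undirected edge -> the two adjacent faces
  std::vector<std::pair<long long, int>> emap;
  auto ue = [](int u, int v) {
    int a = std::min(u, v), b = std::max(u, v);
    return (long long)a * 1000003LL + b;
  };
  for (int f : af) {
    const HFace& F = faces[f];
    emap.push_back({ue(F.a, F.b), f});
    emap.push_back({ue(F.b, F.c), f});
    emap.push_back({ue(F.c, F.a), f});
  }
  std::sort(emap.begin(), emap.end());
  for (size_t q = 0; q + 1 < emap.size(); q += 2) {
    if (emap[q].first != emap[q + 1].first) stop("hull topology error");
    const HFace& F1 = faces[emap[q].second];
    const HFace& F2 = faces[emap[q + 1].second];
    double n1 = std::sqrt(F1.nx * F1.nx + F1.ny * F1.ny + F1.nz * F1.nz);
    double n2 = std::sqrt(F2.nx * F2.nx + F2.ny * F2.ny + F2.nz * F2.nz);
    double cosang = (F1.nx * F2.nx + F1.ny * F2.ny + F1.nz * F2.nz) / (n1 * n2);
    cosang = std::max(-1.0, std::min(1.0, cosang));
    double ang = std::acos(cosang);
    int u = (int)(emap[q].first / 1000003LL), v = (int)(emap[q].first % 1000003LL);
    double ex = P(u, 0) - P(v, 0), ey = P(u, 1) - P(v, 1), ez = P(u, 2) - P(v, 2);
    edgeTerm += std::sqrt(ex * ex + ey * ey + ez * ez) * ang;
  }
  return List::create(_["volume"] = std::fabs(vol), _["area"] = area,
                      _["edge_term"] = edgeTerm, _["n_faces"] = (int)af.size());
}
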