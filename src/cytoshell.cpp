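#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arrays are R arrays in column-major order with dim = (nz, ny, nx):
// index(z, y, x) = z + nz * (y + ny * x).  Axis order (z, y, x) matches the
// acquisition order of confocal stacks and is fixed package-wide.

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform, one axis at a time.
// Lower-envelope-of-parabolas scan (Felzenszwalb & Huttenlocher), equivalent
// to the Maurer et al. exact EDT, generalized to a physical sampling step w
// so that anisotropic voxel spacing is handled exactly.
// ---------------------------------------------------------------------------
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   int n, double w) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never enter the envelope
    double xq = q * w;
    if (k < 0) { k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF; continue; }
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= zb[k]) --k; else break;  // s is finite, zb[0] = -inf, so k >= 0
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  if (k < 0) {  // the whole line is foreground: no information along this axis
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (zb[j + 1] < xq) ++j;
    double xv = v[j] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// mask: logical array (nz, ny, nx); spacing: (dz, dy, dx) in um.
// pad_background: treat the domain outside the array as background one voxel
// step away (the image border convention for cropped single-cell stacks).
// Returns squared distance in um^2 from each voxel center to the nearest
// background voxel center (0 at background voxels).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, NumericVector spacing,
                         bool pad_background) {
  static const double INF = std::numeric_limits<double>::infinity();
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];

  std::vector<double> g((size_t)nz * ny * nx);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    g[i] = mask[i] ? INF : 0.0;

  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) f[z] = g[idx3(z, y, x, nz, ny)];
        bool any_fg = false, all_fg = true;
        for (int z = 0; z < nz; ++z) { if (f[z] == INF) any_fg = true; else all_fg = false; }
        if (!any_fg) continue;
        if (all_fg) { // no background on this line; distances stay INF for now
          continue;
        }
        edt_1d(f, d, nz, dz);
        for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = d[z];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
        edt_1d(f, d, ny, dy);
        for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = d[y];
      }
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
        edt_1d(f, d, nx, dx);
        for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = d[x];
      }
  }

  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = g[i];

  if (pad_background) {
    // border voxels also see virtual background one step outside the array
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          double zeg = std::min(z + 1, nz - z) * dz;
          double yeg = std::min(y + 1, ny - y) * dy;
          double xeg = std::min(x + 1, nx - x) * dx;
          double border = std::min(zeg, std::min(yeg, xeg));
          R_xlen_t i = idx3(z, y, x, nz, ny);
          if (border * border < out[i]) out[i] = border * border;
        }
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected component labeling (BFS).  connectivity: 6 or 26.
// Returns integer array, 0 = background, components numbered from 1 in
// first-encounter (column-major scan) order -> deterministic.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        q.push({z, y, x});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          for (auto& o : offs) {
            int zz = c[0] + o[0], yy = c[1] + o[1], xx = c[2] + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; q.push({zz, yy, xx}); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Per-z-plane hole filling: background 4-connected components (within each
// plane) that do not touch the plane border are flipped to foreground.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_2d(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> outside((size_t)ny * nx);
  std::queue<std::pair<int, int>> q;
  const int oy[4] = {1, -1, 0, 0};
  const int ox[4] = {0, 0, 1, -1};
  for (int z = 0; z < nz; ++z) {
    std::fill(outside.begin(), outside.end(), 0);
    // seed flood fill from all border background pixels of this plane
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        if (!mask[idx3(z, y, x, nz, ny)] && !outside[y + (size_t)ny * x]) {
          outside[y + (size_t)ny * x] = 1;
          q.push({y, x});
          while (!q.empty()) {
            auto c = q.front(); q.pop();
            for (int k = 0; k < 4; ++k) {
              int yy = c.first + oy[k], xx = c.second + ox[k];
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              size_t j = yy + (size_t)ny * xx;
              if (!outside[j] && !mask[idx3(z, yy, xx, nz, ny)]) {
                outside[j] = 1;
                q.push({yy, xx});
              }
            }
          }
        }
      }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (!outside[y + (size_t)ny * x])
          out[idx3(z, y, x, nz, ny)] = TRUE;
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation / erosion with an arbitrary offset list (rows of `offsets`
// are (dz, dy, dx)).  Out-of-bounds neighbors count as background, so
// erosion shrinks the mask at the image border (border-as-background).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerMatrix offsets,
                               bool dilate) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int no = offsets.nrow();
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        bool val = dilate ? false : true;
        for (int k = 0; k < no; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
          bool nb;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            nb = false;
          else
            nb = mask[idx3(zz, yy, xx, nz, ny)];
          if (dilate) { if (nb) { val = true; break; } }
          else        { if (!nb) { val = false; break; } }
        }
        out[i] = val;
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Separable convolution of every z-plane with a 1D kernel along y then x,
// reflected (symmetric) boundary.  Used for the 2D per-plane Gaussian
// smoothing steps.  kernel must have odd length.
// ---------------------------------------------------------------------------
static inline int reflect_idx(int i, int n) {
  // symmetric half-sample reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export]]
NumericVector cpp_conv_planes(NumericVector img, NumericVector ky,
                              NumericVector kx) {
  IntegerVector dim = img.attr("dim");
  if (dim.size() != 3) stop("img must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericVector tmp(img.size()), out(img.size());
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int k = -ry; k <= ry; ++k) {
          int yy = reflect_idx(y + k, ny);
          acc += ky[k + ry] * img[idx3(z, yy, x, nz, ny)];
        }
        tmp[idx3(z, y, x, nz, ny)] = acc;
      }
  // along x
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int k = -rx; k <= rx; ++k) {
          int xx = reflect_idx(x + k, nx);
          acc += kx[k + rx] * tmp[idx3(z, y, xx, nz, ny)];
        }
        out[idx3(z, y, x, nz, ny)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// Convolution along z with a 1D kernel (for the 3D PSF in the simulator).
// [[Rcpp::export]]
NumericVector cpp_conv_z(NumericVector img, NumericVector kz) {
  IntegerVector dim = img.attr("dim");
  if (dim.size() != 3) stop("img must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int rz = (kz.size() - 1) / 2;
  NumericVector out(img.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int k = -rz; k <= rz; ++k) {
          int zz = reflect_idx(z + k, nz);
          acc += kz[k + rz] * img[idx3(zz, y, x, nz, ny)];
        }
        out[idx3(z, y, x, nz, ny)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}
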