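#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 3D connected-component labeling on a logical array stored (z, y, x)
// column-major. connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, int nz, int ny, int nx,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dimensions");
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s: input f at grid positions 0, s, 2s, ...
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sI;
    while (true) {
      double vs = v[k] * s;
      sI = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2 * qs - 2 * vs);
      if (sI <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sI;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (zb[k + 1] < qs) ++k;
    double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a foreground mask, (z, y, x)
// column-major, spacing = (dz, dy, dx) in um. Returns, for each voxel, the
// distance from its center to the nearest background voxel center
// (0 for background voxels).
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, int nz, int ny, int nx,
                        NumericVector spacing) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dimensions");
  if (spacing.size() != 3) stop("spacing must be (dz, dy, dx)");
  // foreground seeds use a large finite value so parabola intersections
  // stay well-defined (lines with no background resolve in later passes)
  const double BIG = 1e30;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = g[base + z];
      f.resize(nz); d.resize(nz);
      dt1d(f, spacing[0], d, v, zb);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = (R_xlen_t)z + (R_xlen_t)nz * ny * x;
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nz * y];
      f.resize(ny); d.resize(ny);
      dt1d(f, spacing[1], d, v, zb);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x (stride nz*ny)
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = (R_xlen_t)z + (R_xlen_t)nz * y;
      R_xlen_t stride = (R_xlen_t)nz * ny;
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = g[base + stride * x];
      f.resize(nx); d.resize(nx);
      dt1d(f, spacing[2], d, v, zb);
      for (int x = 0; x < nx; ++x) g[base + stride * x] = d[x];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    g[i] = g[i] >= 1e29 ? R_PosInf : std::sqrt(g[i]);
  return g;
}
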