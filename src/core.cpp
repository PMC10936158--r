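#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

//' 3D connected-component labelling
//'
//' Labels the connected components of a logical voxel mask by
//' breadth-first search. Adjacency is lattice-based (voxel anisotropy does
//' not enter): 6 connects faces only, 26 also edges and corners.
//'
//' @param mask Logical vector of a 3D array (column-major).
//' @param dims Integer vector, the array dimensions.
//' @param connectivity 6 or 26.
//' @return Integer array of the same shape; 0 is background, components
//'   are numbered from 1 in scan order.
//' @export
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          q.push(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// applied in place along one line. f holds squared distances on input.
static void dt1d(std::vector<double> &f, double spacing) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> zx(n + 1), d(n);
  const double s2 = spacing * spacing;
  int k = 0;
  v[0] = 0;
  zx[0] = -INFINITY;
  zx[1] = INFINITY;
  for (int qi = 1; qi < n; ++qi) {
    double s;
    while (true) {
      s = ((f[qi] + s2 * qi * qi) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * qi - 2.0 * s2 * v[k]);
      if (s <= zx[k]) { --k; } else break;
    }
    ++k;
    v[k] = qi;
    zx[k] = s;
    zx[k + 1] = INFINITY;
  }
  k = 0;
  for (int qi = 0; qi < n; ++qi) {
    while (zx[k + 1] < qi) ++k;
    double dq = (double)(qi - v[k]) * spacing;
    d[qi] = dq * dq + f[v[k]];
  }
  f = d;
}

//' Anisotropic 3D Euclidean distance transform
//'
//' For each foreground voxel, the physical distance (same units as the
//' spacings) to the nearest background voxel centre, computed exactly by
//' the separable lower-envelope algorithm. Voxels outside the array count
//' as background, so objects touching the border are clipped there.
//'
//' @param mask Logical vector of a 3D array (column-major).
//' @param dims Integer vector, the array dimensions.
//' @param dx,dy,dz Voxel spacing along each axis.
//' @return Numeric array of distances; 0 on background.
//' @export
// [[Rcpp::export]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims,
                     double dx, double dy, double dz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double big = 1e30;
  std::vector<double> f((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) f[(size_t)i] = mask[i] ? big : 0.0;

  std::vector<double> line;
  // pass along x (pad with implicit background at both ends via distance to
  // the virtual border voxel)
  line.resize(nx + 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      line[0] = 0.0;
      for (int x = 0; x < nx; ++x) line[x + 1] = f[(size_t)(base + x)];
      line[nx + 1] = 0.0;
      dt1d(line, dx);
      for (int x = 0; x < nx; ++x) f[(size_t)(base + x)] = line[x + 1];
    }
  // pass along y
  line.resize(ny + 2);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      line[0] = 0.0;
      for (int y = 0; y < ny; ++y) line[y + 1] = f[(size_t)(base + (R_xlen_t)y * nx)];
      line[ny + 1] = 0.0;
      dt1d(line, dy);
      for (int y = 0; y < ny; ++y) f[(size_t)(base + (R_xlen_t)y * nx)] = line[y + 1];
    }
  // pass along z
  line.resize(nz + 2);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      line[0] = 0.0;
      for (int z = 0; z < nz; ++z)
        line[z + 1] = f[(size_t)(base + (R_xlen_t)z * nx * ny)];
      line[nz + 1] = 0.0;
      dt1d(line, dz);
      for (int z = 0; z < nz; ++z)
        f[(size_t)(base + (R_xlen_t)z * nx * ny)] = line[z + 1];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(f[(size_t)i]);
  out.attr("dim") = dims;
  return out;
}

//' Zhang-Suen thinning of a 2D binary image
//'
//' Iteratively peels boundary pixels until a 1-pixel-wide skeleton
//' remains. Used per z-plane for thread morphometry.
//'
//' @param img Logical matrix.
//' @return Logical matrix holding the skeleton.
//' @export
// [[Rcpp::export]]
LogicalMatrix thin_2d(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<char> a((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) a[(size_t)j * nr + i] = img(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return a[(size_t)j * nr + i];
  };

  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!at(i, j)) continue;
          // neighbours p2..p9 clockwise starting above
          char p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
               p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
               p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int acount = 0;
          char seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++acount;
          if (acount != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back({i, j});
        }
      for (auto &p : del) a[(size_t)p.second * nr + p.first] = 0;
      if (!del.empty()) changed = true;
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = a[(size_t)j * nr + i] != 0;
  return out;
}
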