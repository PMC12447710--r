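#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), with
// anisotropic voxel spacing in mm. Returns, per voxel, the distance to the
// nearest foreground voxel (centre-to-centre, mm). All-background input
// yields +Inf everywhere.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, int n, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  // lower envelope of parabolas rooted at finite samples only
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    const double xq = q * h;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INFINITY;
      z[1] = INFINITY;
      continue;
    }
    double s;
    for (;;) {
      const double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * h;
    while (z[j + 1] < xq) ++j;
    const double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INFINITY;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  for (int zz = 0; zz < Z; ++zz)
    for (int yy = 0; yy < Y; ++yy) {
      size_t base = (size_t)X * (yy + (size_t)Y * zz);
      for (int xx = 0; xx < X; ++xx) f[xx] = g[base + xx];
      dt1d(f, X, spacing[0], d, v, z);
      for (int xx = 0; xx < X; ++xx) g[base + xx] = d[xx];
    }
  // y axis
  for (int zz = 0; zz < Z; ++zz)
    for (int xx = 0; xx < X; ++xx) {
      for (int yy = 0; yy < Y; ++yy) f[yy] = g[xx + (size_t)X * (yy + (size_t)Y * zz)];
      dt1d(f, Y, spacing[1], d, v, z);
      for (int yy = 0; yy < Y; ++yy) g[xx + (size_t)X * (yy + (size_t)Y * zz)] = d[yy];
    }
  // z axis
  for (int yy = 0; yy < Y; ++yy)
    for (int xx = 0; xx < X; ++xx) {
      for (int zz = 0; zz < Z; ++zz) f[zz] = g[xx + (size_t)X * (yy + (size_t)Y * zz)];
      dt1d(f, Z, spacing[2], d, v, z);
      for (int zz = 0; zz < Z; ++zz) g[xx + (size_t)X * (yy + (size_t)Y * zz)] = d[zz];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential 3-D thinning (26-connected foreground,
// 6-connected background). A voxel is simple (Malandain-Bertrand
// characterisation) iff it has exactly one 26-connected foreground component
// in its 26-neighbourhood and exactly one 6-connected background component
// in its 18-neighbourhood touching a face neighbour. Curve endpoints
// (exactly one foreground neighbour) are preserved, yielding a one-voxel
// centerline for tubular shapes.
// ---------------------------------------------------------------------------

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

static int fg_components26(const bool* nb) {
  // connected components (26-adjacency) of foreground among the 26 neighbours
  bool lab[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || lab[i]) continue;
    ++comps;
    int top = 0;
    stack[top++] = i;
    lab[i] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
            int j = nx + 3 * (ny + 3 * nz);
            if (j == 13 || j == cur || lab[j] || !nb[j]) continue;
            lab[j] = true;
            stack[top++] = j;
          }
    }
  }
  return comps;
}

static int bg_components6(const bool* nb) {
  // 6-connected background components within the 18-neighbourhood that are
  // 6-adjacent to the centre
  bool lab[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int manh = std::abs(x) + std::abs(y) + std::abs(z);
    if (manh != 1) continue;  // seed only from face neighbours
    if (nb[i] || lab[i]) continue;
    ++comps;
    int top = 0;
    stack[top++] = i;
    lab[i] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int fidx = 0; fidx < 6; ++fidx) {
        int nx = cx + face[fidx][0], ny = cy + face[fidx][1], nz = cz + face[fidx][2];
        if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
        int j = nx + 3 * (ny + 3 * nz);
        int jx = nx - 1, jy = ny - 1, jz = nz - 1;
        if (std::abs(jx) + std::abs(jy) + std::abs(jz) > 2) continue;  // stay in N18
        if (j == 13 || lab[j] || nb[j]) continue;
        lab[j] = true;
        stack[top++] = j;
      }
    }
  }
  return comps;
}

static inline void fill_nb(const int* img, int X, int Y, int Z,
                           int x, int y, int z, bool* nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool val = false;
        if (xx >= 0 && xx < X && yy >= 0 && yy < Y && zz >= 0 && zz < Z)
          val = img[xx + (size_t)X * (yy + (size_t)Y * zz)] != 0;
        nb[nb_index(dx, dy, dz)] = val;
      }
}

static inline int count_nb26(const bool* nb) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t n = (size_t)X * Y * Z;
  std::vector<int> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  std::vector<size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x = 0; x < X; ++x) {
            size_t i = x + (size_t)X * (y + (size_t)Y * z);
            if (!img[i]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            bool border = !(bx >= 0 && bx < X && by >= 0 && by < Y && bz >= 0 && bz < Z) ||
                          img[bx + (size_t)X * (by + (size_t)Y * bz)] == 0;
            if (!border) continue;
            cand.push_back(i);
          }
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        size_t i = cand[ci];
        if (!img[i]) continue;
        int x = (int)(i % X), y = (int)((i / X) % Y), z = (int)(i / ((size_t)X * Y));
        fill_nb(img.data(), X, Y, Z, x, y, z, nb);
        int nn = count_nb26(nb);
        if (nn <= 1) continue;  // endpoint or isolated: keep
        if (fg_components26(nb) != 1) continue;
        if (bg_components6(nb) != 1) continue;
        img[i] = 0;  // simple: delete (sequential, so topology is preserved)
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
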