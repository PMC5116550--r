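// Low-level 3D voxel primitives: connected components, Euler characteristic
// via a generated octant lookup table, simple-point tests, curve thinning,
// exact anisotropic Euclidean feature transform, separable Gaussian
// smoothing with Hessian eigenvalues, and cube-kernel binary morphology.
//
// Conventions: volumes are column-major with dim = (nx, ny, nz); linear
// index (0-based, C++ side) is x + nx*(y + ny*z). Out-of-grid voxels are
// background for every predicate.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  bool in(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  int idx(int x, int y, int z) const { return lin(x, y, z, nx, ny); }
  void coords(int i, int &x, int &y, int &z) const {
    x = i % nx; y = (i / nx) % ny; z = i / (nx * ny);
  }
};

// 26-neighborhood offsets, lexicographic in (dz, dy, dx) nesting but any
// fixed order works; adjacency class = number of nonzero components.
static void offsets26(std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off.push_back({dx, dy, dz});
      }
}

static const int OFF6[6][3] = {
  {0, 0, 1}, {0, 0, -1}, {0, 1, 0}, {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}
};

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS in ascending linear-index order, so
// labels are deterministic: component containing the smallest index is 1).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g(dim);
  const int n = g.nx * g.ny * g.nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  if (connectivity == 26) {
    offsets26(off);
  } else {
    for (int k = 0; k < 6; ++k) off.push_back({OFF6[k][0], OFF6[k][1], OFF6[k][2]});
  }
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int x, y, z; g.coords(cur, x, y, z);
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (!g.in(xx, yy, zz)) continue;
        int j = g.idx(xx, yy, zz);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Euler characteristic under the (26 foreground, 6 background) convention.
//
// The union of closed unit cubes of the foreground voxels realizes this
// convention; chi = V - E + F - C over its cubical complex. Every cell with
// minimal grid vertex p is owned by the 2x2x2 voxel window at p - (1,1,1),
// and all voxels determining its presence lie in that window, so chi is a
// sum over windows of a 256-entry table generated here from first
// principles (no copied table).
// ---------------------------------------------------------------------------

static int G_TABLE[256];
static bool G_READY = false;

static inline int wbit(int lx, int ly, int lz) { return lx + 2 * ly + 4 * lz; }

static void build_g_table() {
  if (G_READY) return;
  for (int cfg = 0; cfg < 256; ++cfg) {
    bool vox[8];
    for (int b = 0; b < 8; ++b) vox[b] = (cfg >> b) & 1;
    // Owned vertex: the grid point shared by all 8 window voxels.
    int v = (cfg != 0) ? 1 : 0;
    // Owned edges: min vertex at window center, one per axis a; present iff
    // any voxel with local coordinate 1 along a.
    int e = 0;
    for (int a = 0; a < 3; ++a) {
      bool present = false;
      for (int b = 0; b < 8; ++b) {
        int l[3] = { b & 1, (b >> 1) & 1, (b >> 2) & 1 };
        if (vox[b] && l[a] == 1) { present = true; break; }
      }
      if (present) ++e;
    }
    // Owned faces: normal a; present iff any voxel with both other local
    // coordinates equal to 1.
    int f = 0;
    for (int a = 0; a < 3; ++a) {
      bool present = false;
      for (int b = 0; b < 8; ++b) {
        int l[3] = { b & 1, (b >> 1) & 1, (b >> 2) & 1 };
        if (vox[b] && l[(a + 1) % 3] == 1 && l[(a + 2) % 3] == 1) { present = true; break; }
      }
      if (present) ++f;
    }
    // Owned cube: the voxel at local (1,1,1).
    int c = vox[wbit(1, 1, 1)] ? 1 : 0;
    G_TABLE[cfg] = v - e + f - c;
  }
  G_READY = true;
}

static inline bool fg(const std::vector<char> &m, const Grid &g, int x, int y, int z) {
  return g.in(x, y, z) && m[g.idx(x, y, z)];
}

// chi of the whole volume.
static int chi_of(const std::vector<char> &m, const Grid &g) {
  build_g_table();
  int chi = 0;
  for (int wz = -1; wz < g.nz; ++wz)
    for (int wy = -1; wy < g.ny; ++wy)
      for (int wx = -1; wx < g.nx; ++wx) {
        int cfg = 0;
        for (int b = 0; b < 8; ++b) {
          int lx = b & 1, ly = (b >> 1) & 1, lz = (b >> 2) & 1;
          if (fg(m, g, wx + lx, wy + ly, wz + lz)) cfg |= (1 << b);
        }
        if (cfg) chi += G_TABLE[cfg];
      }
  return chi;
}

// [[Rcpp::export(name = ".euler_chi_cpp")]]
int euler_chi_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  return chi_of(m, g);
}

// Change in chi when voxel v is removed: only the 8 windows containing v
// change configuration.
static int delta_chi_remove(const std::vector<char> &m, const Grid &g, int x, int y, int z) {
  build_g_table();
  int d = 0;
  for (int wz = z - 1; wz <= z; ++wz)
    for (int wy = y - 1; wy <= y; ++wy)
      for (int wx = x - 1; wx <= x; ++wx) {
        int cfgOn = 0, bitv = -1;
        for (int b = 0; b < 8; ++b) {
          int lx = b & 1, ly = (b >> 1) & 1, lz = (b >> 2) & 1;
          int xx = wx + lx, yy = wy + ly, zz = wz + lz;
          if (xx == x && yy == y && zz == z) bitv = b;
          if (fg(m, g, xx, yy, zz)) cfgOn |= (1 << b);
        }
        int cfgOff = cfgOn & ~(1 << bitv);
        d += G_TABLE[cfgOff] - G_TABLE[cfgOn];
      }
  return d; // chi(after removal) - chi(before)
}

// [[Rcpp::export(name = ".delta_chi_cpp")]]
int delta_chi_cpp(LogicalVector mask, IntegerVector dim, int idx0) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  int x, y, z; g.coords(idx0, x, y, z);
  return delta_chi_remove(m, g, x, y, z);
}

// ---------------------------------------------------------------------------
// Simple-point test: number of 26-connected foreground components of the
// 3x3x3 patch is unchanged by removing the centre voxel.
// ---------------------------------------------------------------------------

static int patch_components(const bool patch[27]) {
  int lab[27]; for (int i = 0; i < 27; ++i) lab[i] = 0;
  int comp = 0;
  for (int i = 0; i < 27; ++i) {
    if (!patch[i] || lab[i]) continue;
    ++comp;
    std::queue<int> q; q.push(i); lab[i] = comp;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
            int j = xx + 3 * yy + 9 * zz;
            if (patch[j] && !lab[j]) { lab[j] = comp; q.push(j); }
          }
    }
  }
  return comp;
}

static bool simple_at(const std::vector<char> &m, const Grid &g, int x, int y, int z) {
  bool with[27], without[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int j = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        bool f = fg(m, g, x + dx, y + dy, z + dz);
        with[j] = f;
        without[j] = f;
      }
  without[13] = false;
  return patch_components(with) == patch_components(without);
}

// [[Rcpp::export(name = ".is_simple_cpp")]]
bool is_simple_cpp(LogicalVector mask, IntegerVector dim, int idx0) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  int x, y, z; g.coords(idx0, x, y, z);
  return simple_at(m, g, x, y, z);
}

static int nbr26_count(const std::vector<char> &m, const Grid &g, int x, int y, int z) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (fg(m, g, x + dx, y + dy, z + dz)) ++c;
      }
  return c;
}

// [[Rcpp::export(name = ".nbr26_count_cpp")]]
IntegerVector nbr26_count_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  const int n = g.nx * g.ny * g.nz;
  IntegerVector out(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!m[i]) continue;
    int x, y, z; g.coords(i, x, y, z);
    out[i] = nbr26_count(m, g, x, y, z);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Curve thinning: iteratively delete voxels that are simultaneously Border
// (in the current sweep direction), Line, Euler-invariant and Simple.
// Six directional subiterations per pass; within a subiteration candidates
// are collected first and then deleted sequentially in ascending linear
// index order with the Line/Euler/Simple conditions rechecked at deletion
// time, which guarantees topology preservation.
//
// A border candidate must also have its opposite 6-neighbour in the
// foreground. Without this, a structure that is one voxel thick in the
// sweep direction has every voxel as a candidate, and sequential deletion
// unzips it end to end (each interior voxel stays simple and never becomes
// a line end while its partner column survives), erasing whole branches of
// axis-symmetric tubes. Requiring a foreground opposite neighbour limits
// each subiteration to peeling a single one-voxel shell.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalVector thin_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  build_g_table();
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      const int n = g.nx * g.ny * g.nz;
      for (int i = 0; i < n; ++i) {
        if (!m[i]) continue;
        int x, y, z; g.coords(i, x, y, z);
        // Border in direction d: that face neighbour is background and the
        // opposite face neighbour is foreground. Voxels attached to the
        // object only diagonally (no foreground face neighbour at all)
        // would otherwise never be candidates; they are admitted in every
        // direction, which cannot unzip a ladder because ladder voxels
        // always keep a foreground face partner.
        if (fg(m, g, x + OFF6[d][0], y + OFF6[d][1], z + OFF6[d][2])) continue;
        if (!fg(m, g, x - OFF6[d][0], y - OFF6[d][1], z - OFF6[d][2])) {
          bool anyFace = false;
          for (int q = 0; q < 6 && !anyFace; ++q)
            anyFace = fg(m, g, x + OFF6[q][0], y + OFF6[q][1], z + OFF6[q][2]);
          if (anyFace) continue;
        }
        if (nbr26_count(m, g, x, y, z) <= 1) continue;          // Line voxel
        if (delta_chi_remove(m, g, x, y, z) != 0) continue;     // Euler invariant
        if (!simple_at(m, g, x, y, z)) continue;                // Simple voxel
        cand.push_back(i);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int x, y, z; g.coords(i, x, y, z);
        if (nbr26_count(m, g, x, y, z) <= 1) continue;
        if (delta_chi_remove(m, g, x, y, z) != 0) continue;
        if (!simple_at(m, g, x, y, z)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(m.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean feature transform (Felzenszwalb-Huttenlocher lower
// envelope, one pass per axis, anisotropic spacing) with nearest-seed
// tracking. After the passes the squared distance is recomputed from the
// nearest-seed coordinates as dx^2*sx^2 + dy^2*sy^2 + dz^2*sz^2 (fixed
// summation order) so that values agree bitwise with a direct evaluation.
// ---------------------------------------------------------------------------

static const double BIG = 1e30;

// Full 3D feature transform. seeds: logical mask of seed voxels.
// Returns list(dist2, seed) where seed is 1-based linear index (NA if none).
// [[Rcpp::export(name = ".feature_transform_cpp")]]
List feature_transform_cpp(LogicalVector seeds, IntegerVector dim, NumericVector spacing) {
  Grid g(dim);
  const int n = g.nx * g.ny * g.nz;
  std::vector<double> f(n);
  std::vector<int> arg(n);
  for (int i = 0; i < n; ++i) {
    if (seeds[i]) { f[i] = 0.0; arg[i] = i; }
    else { f[i] = BIG; arg[i] = -1; }
  }

  int dims[3] = { g.nx, g.ny, g.nz };
  int strides[3] = { 1, g.nx, g.nx * g.ny };

  std::vector<int> v; std::vector<double> zb; std::vector<double> fl;
  std::vector<int> al; std::vector<double> ol; std::vector<int> aol;

  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const int stride = strides[axis];
    const double s = spacing[axis];
    v.assign(len, 0); zb.assign(len + 1, 0.0);
    fl.assign(len, 0.0); al.assign(len, 0); ol.assign(len, 0.0); aol.assign(len, 0);
    // Iterate over all lines along `axis`.
    int o1 = (axis == 0) ? 1 : 0;
    int o2 = (axis == 2) ? 1 : 2;
    for (int b = 0; b < dims[o2]; ++b) {
      for (int a = 0; a < dims[o1]; ++a) {
        int base = a * strides[o1] + b * strides[o2];
        bool any = false;
        for (int q = 0; q < len; ++q) {
          fl[q] = f[base + q * stride];
          al[q] = arg[base + q * stride];
          if (fl[q] < BIG) any = true;
        }
        if (!any) continue;
        // Lower envelope of parabolas y = (x - q*s)^2 + fl[q].
        int k = 0;
        v[0] = 0;
        // Skip leading BIG entries by seeding with first finite parabola.
        int first = 0;
        while (fl[first] >= BIG) ++first;
        v[0] = first;
        zb[0] = -BIG; zb[1] = BIG;
        auto intersect = [&](int q, int p) {
          double xq = q * s, xp = p * s;
          return ((fl[q] + xq * xq) - (fl[p] + xp * xp)) / (2.0 * xq - 2.0 * xp);
        };
        for (int q = first + 1; q < len; ++q) {
          if (fl[q] >= BIG) continue;
          double sIntersect = intersect(q, v[k]);
          while (sIntersect <= zb[k]) {
            --k;
            sIntersect = intersect(q, v[k]);
          }
          ++k; v[k] = q; zb[k] = sIntersect; zb[k + 1] = BIG;
        }
        int kk = 0;
        for (int q = 0; q < len; ++q) {
          double xq = q * s;
          while (zb[kk + 1] < xq) ++kk;
          int p = v[kk];
          double xp = p * s;
          ol[q] = (xq - xp) * (xq - xp) + fl[p];
          aol[q] = al[p];
        }
        for (int q = 0; q < len; ++q) {
          f[base + q * stride] = ol[q];
          arg[base + q * stride] = aol[q];
        }
      }
    }
  }

  // Recompute exact squared distances from the nearest-seed coordinates.
  NumericVector dist2(n);
  IntegerVector seedOut(n);
  const double sx2 = spacing[0] * spacing[0];
  const double sy2 = spacing[1] * spacing[1];
  const double sz2 = spacing[2] * spacing[2];
  for (int i = 0; i < n; ++i) {
    if (arg[i] < 0) { dist2[i] = NA_REAL; seedOut[i] = NA_INTEGER; continue; }
    int x, y, z, xs, ys, zs;
    g.coords(i, x, y, z);
    g.coords(arg[i], xs, ys, zs);
    double dx = x - xs, dy = y - ys, dz = z - zs;
    dist2[i] = dx * dx * sx2 + dy * dy * sy2 + dz * dz * sz2;
    seedOut[i] = arg[i] + 1;
  }
  return List::create(_["dist2"] = dist2, _["seed"] = seedOut);
}

// Brute-force nearest-seed labelling (test oracle; naive triple loop).
// seeds: 1-based linear indices; labels: integer label per seed.
// Ties resolved to the lowest label, then lowest seed index (seeds must be
// supplied sorted by (label, index)).
// [[Rcpp::export(name = ".bf_nearest_label_cpp")]]
List bf_nearest_label_cpp(IntegerVector dim, IntegerVector seeds, IntegerVector labels,
                          NumericVector spacing, IntegerVector query) {
  Grid g(dim);
  const int m = seeds.size();
  const int nq = query.size();
  IntegerVector lab(nq);
  NumericVector d2(nq);
  const double sx2 = spacing[0] * spacing[0];
  const double sy2 = spacing[1] * spacing[1];
  const double sz2 = spacing[2] * spacing[2];
  std::vector<int> sx(m), sy(m), sz(m);
  for (int j = 0; j < m; ++j) {
    int x, y, z; g.coords(seeds[j] - 1, x, y, z);
    sx[j] = x; sy[j] = y; sz[j] = z;
  }
  for (int qi = 0; qi < nq; ++qi) {
    int x, y, z; g.coords(query[qi] - 1, x, y, z);
    double best = std::numeric_limits<double>::infinity();
    int bestLab = NA_INTEGER;
    for (int j = 0; j < m; ++j) {
      double dx = x - sx[j], dy = y - sy[j], dz = z - sz[j];
      double d = dx * dx * sx2 + dy * dy * sy2 + dz * dz * sz2;
      if (d < best) { best = d; bestLab = labels[j]; }
    }
    lab[qi] = bestLab;
    d2[qi] = best;
  }
  return List::create(_["label"] = lab, _["dist2"] = d2);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (reflective boundary) and Hessian eigenvalues.
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &vol, const Grid &g, int axis, double sigmaVox) {
  if (sigmaVox <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigmaVox));
  std::vector<double> w(2 * r + 1);
  double sum = 0;
  for (int k = -r; k <= r; ++k) {
    w[k + r] = std::exp(-0.5 * k * k / (sigmaVox * sigmaVox));
    sum += w[k + r];
  }
  for (auto &x : w) x /= sum;
  int dims[3] = { g.nx, g.ny, g.nz };
  int strides[3] = { 1, g.nx, g.nx * g.ny };
  const int len = dims[axis], stride = strides[axis];
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(len), out(len);
  for (int b = 0; b < dims[o2]; ++b)
    for (int a = 0; a < dims[o1]; ++a) {
      int base = a * strides[o1] + b * strides[o2];
      for (int q = 0; q < len; ++q) line[q] = vol[base + q * stride];
      for (int q = 0; q < len; ++q) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int p = q + k;
          if (p < 0) p = -p - 1;          // reflect
          if (p >= len) p = 2 * len - p - 1;
          if (p < 0) p = 0;               // degenerate tiny axes
          if (p >= len) p = len - 1;
          acc += w[k + r] * line[p];
        }
        out[q] = acc;
      }
      for (int q = 0; q < len; ++q) vol[base + q * stride] = out[q];
    }
}

// [[Rcpp::export(name = ".gaussian_smooth_cpp")]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, double sigmaMM) {
  Grid g(dim);
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(v, g, axis, sigmaMM / spacing[axis]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix, closed form.
static void sym3_eigs(double a11, double a22, double a33,
                      double a12, double a13, double a23, double eig[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    eig[0] = a11; eig[1] = a22; eig[2] = a33;
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) + (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13)
              + b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  double e2 = 3.0 * q - e1 - e3;
  eig[0] = e1; eig[1] = e2; eig[2] = e3;
}

// Hessian eigenvalues of a Gaussian-smoothed volume at one scale, sorted by
// absolute value (|l1| <= |l2| <= |l3|), gamma-normalised by sigma^2.
// [[Rcpp::export(name = ".hessian_eig_cpp")]]
List hessian_eig_cpp(NumericVector vol, IntegerVector dim,
                     NumericVector spacing, double sigmaMM) {
  Grid g(dim);
  const int n = g.nx * g.ny * g.nz;
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(v, g, axis, sigmaMM / spacing[axis]);

  NumericVector l1(n), l2(n), l3(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double norm = sigmaMM * sigmaMM;
  auto at = [&](int x, int y, int z) {
    if (x < 0) x = 0; if (x >= g.nx) x = g.nx - 1;
    if (y < 0) y = 0; if (y >= g.ny) y = g.ny - 1;
    if (z < 0) z = 0; if (z >= g.nz) z = g.nz - 1;
    return v[g.idx(x, y, z)];
  };
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        double c = at(x, y, z);
        double hxx = (at(x + 1, y, z) - 2 * c + at(x - 1, y, z)) / (sx * sx);
        double hyy = (at(x, y + 1, z) - 2 * c + at(x, y - 1, z)) / (sy * sy);
        double hzz = (at(x, y, z + 1) - 2 * c + at(x, y, z - 1)) / (sz * sz);
        double hxy = (at(x + 1, y + 1, z) - at(x + 1, y - 1, z)
                      - at(x - 1, y + 1, z) + at(x - 1, y - 1, z)) / (4 * sx * sy);
        double hxz = (at(x + 1, y, z + 1) - at(x + 1, y, z - 1)
                      - at(x - 1, y, z + 1) + at(x - 1, y, z - 1)) / (4 * sx * sz);
        double hyz = (at(x, y + 1, z + 1) - at(x, y + 1, z - 1)
                      - at(x, y - 1, z + 1) + at(x, y - 1, z - 1)) / (4 * sy * sz);
        double eig[3];
        sym3_eigs(norm * hxx, norm * hyy, norm * hzz,
                  norm * hxy, norm * hxz, norm * hyz, eig);
        // sort by |.|
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2 - a; ++b)
            if (std::fabs(eig[b]) > std::fabs(eig[b + 1])) std::swap(eig[b], eig[b + 1]);
        int i = g.idx(x, y, z);
        l1[i] = eig[0]; l2[i] = eig[1]; l3[i] = eig[2];
      }
  l1.attr("dim") = dim; l2.attr("dim") = dim; l3.attr("dim") = dim;
  return List::create(_["lambda1"] = l1, _["lambda2"] = l2, _["lambda3"] = l3);
}

// ---------------------------------------------------------------------------
// Binary morphology with a 3x3x3 cube structuring element.
// ---------------------------------------------------------------------------

static void dilate_cube(std::vector<char> &m, const Grid &g) {
  std::vector<char> src(m);
  const int n = g.nx * g.ny * g.nz;
  for (int i = 0; i < n; ++i) {
    if (src[i]) { m[i] = 1; continue; }
    int x, y, z; g.coords(i, x, y, z);
    bool any = false;
    for (int dz = -1; dz <= 1 && !any; ++dz)
      for (int dy = -1; dy <= 1 && !any; ++dy)
        for (int dx = -1; dx <= 1 && !any; ++dx)
          if (fg(src, g, x + dx, y + dy, z + dz)) any = true;
    m[i] = any ? 1 : 0;
  }
}

static void erode_cube(std::vector<char> &m, const Grid &g) {
  std::vector<char> src(m);
  const int n = g.nx * g.ny * g.nz;
  for (int i = 0; i < n; ++i) {
    if (!src[i]) { m[i] = 0; continue; }
    int x, y, z; g.coords(i, x, y, z);
    bool all = true;
    for (int dz = -1; dz <= 1 && all; ++dz)
      for (int dy = -1; dy <= 1 && all; ++dy)
        for (int dx = -1; dx <= 1 && all; ++dx)
          if (!fg(src, g, x + dx, y + dy, z + dz)) all = false;
    m[i] = all ? 1 : 0;
  }
}

// [[Rcpp::export(name = ".binary_closing_cpp")]]
LogicalVector binary_closing_cpp(LogicalVector mask, IntegerVector dim, int iterations) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  for (int it = 0; it < iterations; ++it) dilate_cube(m, g);
  for (int it = 0; it < iterations; ++it) erode_cube(m, g);
  LogicalVector out(m.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// 26-adjacency pairs among foreground voxels, 1-based linear indices, i < j.
// [[Rcpp::export(name = ".skel_adjacency_cpp")]]
IntegerMatrix skel_adjacency_cpp(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  std::vector<char> m(mask.begin(), mask.end());
  const int n = g.nx * g.ny * g.nz;
  std::vector<int> from, to;
  for (int i = 0; i < n; ++i) {
    if (!m[i]) continue;
    int x, y, z; g.coords(i, x, y, z);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (!g.in(xx, yy, zz)) continue;
          int j = g.idx(xx, yy, zz);
          if (j > i && m[j]) { from.push_back(i + 1); to.push_back(j + 1); }
        }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t k = 0; k < from.size(); ++k) { out(k, 0) = from[k]; out(k, 1) = to[k]; }
  return out;
}
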