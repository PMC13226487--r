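#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, with per-axis sample spacing so anisotropic voxels are handled
// exactly.  Input f: 0 at source voxels, +Inf elsewhere.
// ---------------------------------------------------------------------------

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(const double *f, double *d, int n, double w) {
  // lower envelope of parabolas y = f[i] + (w*(q - i))^2
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(NumericVector f, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(clone(f));
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), dbuf(nmax);

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double *col = &out[0] + (size_t)nx * (y + (size_t)ny * z);
      dt1d(col, dbuf.data(), nx, spacing[0]);
      std::copy(dbuf.begin(), dbuf.begin() + nx, col);
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y)
        buf[y] = out[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(buf.data(), dbuf.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y)
        out[x + (size_t)nx * (y + (size_t)ny * z)] = dbuf[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z)
        buf[z] = out[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(buf.data(), dbuf.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z)
        out[x + (size_t)nx * (y + (size_t)ny * z)] = dbuf[z];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity), BFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && m != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = dx.size();

  int next = 0;
  std::queue<size_t> q;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      size_t v = q.front(); q.pop();
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int k = 0; k < nn; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t w = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning: iterative removal of simple border points
// (Bertrand-Malandain simpleness test) in six directional subiterations,
// keeping curve endpoints, until a fixed point is reached.
// ---------------------------------------------------------------------------

// local flood fill over a 3x3x3 patch, returns number of components among
// cells where sel[] is true, using the given connectivity (6 or 26)
static int local_cc(const bool *sel, int connectivity, const bool *restrict_to) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!sel[s] || seen[s]) continue;
    if (restrict_to && !restrict_to[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int ez = -1; ez <= 1; ++ez)
        for (int ey = -1; ey <= 1; ++ey)
          for (int ex = -1; ex <= 1; ++ex) {
            int m = std::abs(ex) + std::abs(ey) + std::abs(ez);
            if (m == 0) continue;
            if (connectivity == 6 && m != 1) continue;
            int xx = cx + ex, yy = cy + ey, zz = cz + ez;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2)
              continue;
            int w = xx + 3 * yy + 9 * zz;
            if (sel[w] && !seen[w]) { seen[w] = true; stack[top++] = w; }
          }
    }
  }
  return ncomp;
}

// grow each background component found in N18 so membership is decided
// within N18, seeded only from the 6-neighbours of the center
static int bg_cc_n18(const bool *bg) {
  // cells of the 18-neighbourhood (exclude corners and center)
  bool in18[27], seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    int cx = s % 3 - 1, cy = (s / 3) % 3 - 1, cz = s / 9 - 1;
    int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
    in18[s] = (m == 1 || m == 2);
  }
  static const int six[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  int ncomp = 0, stack[27];
  for (int k = 0; k < 6; ++k) {
    int s = six[k];
    if (!bg[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int ex[6] = {1, -1, 0, 0, 0, 0};
      static const int ey[6] = {0, 0, 1, -1, 0, 0};
      static const int ez[6] = {0, 0, 0, 0, 1, -1};
      for (int k2 = 0; k2 < 6; ++k2) {
        int xx = cx + ex[k2], yy = cy + ey[k2], zz = cz + ez[k2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int w = xx + 3 * yy + 9 * zz;
        if (w == 13) continue;
        if (bg[w] && in18[w] && !seen[w]) { seen[w] = true; stack[top++] = w; }
      }
    }
  }
  return ncomp;
}

struct Vol {
  const int nx, ny, nz;
  std::vector<char> d;
  Vol(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_),
    d((size_t)nx_ * ny_ * nz_, 0) {}
  inline char at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return d[x + (size_t)nx * (y + (size_t)ny * z)];
  }
  inline void set(size_t i, char v) { d[i] = v; }
};

static bool is_simple(const Vol &v, int x, int y, int z) {
  bool fg[27], bg[27];
  int nfg = 0;
  for (int s = 0; s < 27; ++s) {
    int cx = s % 3 - 1, cy = (s / 3) % 3 - 1, cz = s / 9 - 1;
    bool f = v.at(x + cx, y + cy, z + cz) != 0;
    fg[s] = f;
    bg[s] = !f;
    if (s != 13 && f) ++nfg;
  }
  if (nfg == 0) return false;          // isolated point: keep
  fg[13] = false;                      // exclude center from fg components
  if (local_cc(fg, 26, NULL) != 1) return false;
  if (bg_cc_n18(bg) != 1) return false;
  return true;
}

static int n26_count(const Vol &v, int x, int y, int z) {
  int n = 0;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (!cx && !cy && !cz) continue;
        if (v.at(x + cx, y + cy, z + cz)) ++n;
      }
  return n;
}

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Vol v(nx, ny, nz);
  const size_t n = (size_t)nx * ny * nz;
  for (size_t i = 0; i < n; ++i) v.set(i, mask[i] ? 1 : 0);

  // face-direction offsets: U, D, N, S, E, W
  static const int ddx[6] = {0, 0, 0, 0, 1, -1};
  static const int ddy[6] = {0, 0, 1, -1, 0, 0};
  static const int ddz[6] = {1, -1, 0, 0, 0, 0};

  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<size_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t i = x + (size_t)nx * (y + (size_t)ny * z);
            if (!v.d[i]) continue;
            if (v.at(x + ddx[dir], y + ddy[dir], z + ddz[dir])) continue;
            if (n26_count(v, x, y, z) <= 1) continue;  // endpoint
            if (is_simple(v, x, y, z)) cand.push_back(i);
          }
      // sequential deletion with re-check keeps topology exact
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t i = cand[k];
        int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
        if (n26_count(v, x, y, z) <= 1) continue;
        if (is_simple(v, x, y, z)) { v.set(i, 0); changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = v.d[i] != 0;
  out.attr("dim") = dims;
  return out;
}
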