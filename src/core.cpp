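#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Voxel topology kernels. Convention throughout: foreground uses
// 26-connectivity, background 6-connectivity (the standard complementary
// pair that avoids connectivity paradoxes on the cubic grid).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-connected components of the foreground restricted to the 3x3x3
// neighbourhood minus the centre. nb is a 27-long 0/1 array (centre = 13).
static int count_fg_components26(const int nb[27]) {
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || lab[i]) continue;
    ++ncomp;
    std::queue<int> q; q.push(i); lab[i] = ncomp;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int j = x + 3 * y + 9 * z;
            if (j == 13 || j == c || !nb[j] || lab[j]) continue;
            lab[j] = ncomp; q.push(j);
          }
    }
  }
  return ncomp;
}

// 6-connected components of the background restricted to the 18-neighbourhood
// (face+edge neighbours), counting only components 6-adjacent to the centre.
static int count_bg_components6(const int nb[27]) {
  // 18-neighbourhood: offsets with Chebyshev distance 1 and |dx|+|dy|+|dz|<=2
  bool in18[27]; int lab[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int s = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (i != 13) && (s <= 2);
    lab[i] = 0;
  }
  int ncomp = 0;
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  for (int f = 0; f < 6; ++f) {
    int i = face[f];
    if (nb[i] || lab[i]) continue;  // want background seeds adjacent to centre
    ++ncomp;
    std::queue<int> q; q.push(i); lab[i] = ncomp;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int x = cx + d6[k][0], y = cy + d6[k][1], z = cz + d6[k][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int j = x + 3 * y + 9 * z;
        if (!in18[j] || nb[j] || lab[j]) continue;
        lab[j] = ncomp; q.push(j);
      }
    }
  }
  return ncomp;
}

static inline void fill_neighbourhood(const LogicalVector& vol, int x, int y,
                                      int z, int nx, int ny, int nz, int nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int X = x + dx, Y = y + dy, Z = z + dz;
        nb[i] = (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
          ? (vol[idx3(X, Y, Z, nx, ny)] ? 1 : 0) : 0;
      }
}

static inline bool is_simple(const int nb[27]) {
  return count_fg_components26(nb) == 1 && count_bg_components6(nb) == 1;
}

static inline int n_fg_neighbours26(const int nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++n;
  return n;
}

// [[Rcpp::export]]
LogicalVector simple_points_cpp(LogicalVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(vol.size());
  int nb[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!vol[i]) { out[i] = false; continue; }
        fill_neighbourhood(vol, x, y, z, nx, ny, nz, nb);
        out[i] = is_simple(nb);
      }
  return out;
}

// Curve-skeleton thinning: iteratively delete simple, non-endpoint border
// voxels in six directional sub-iterations (U, D, N, S, E, W) until stable.
// Deletion is sequential within a sub-iteration with the simple-point test
// re-evaluated on the current object, so each removal provably preserves
// the number of 26-components, tunnels and cavities. Endpoints (exactly one
// 26-neighbour) are retained so that line-like objects keep their length.
// [[Rcpp::export]]
LogicalVector thin_volume_cpp(LogicalVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector cur = clone(vol);
  static const int dirs[6][3] = {
    {0, 0, 1}, {0, 0, -1}, {0, 1, 0}, {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}};
  int nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collect candidates whose d-direction face neighbour is background
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (!cur[i]) continue;
            int X = x + dirs[d][0], Y = y + dirs[d][1], Z = z + dirs[d][2];
            bool bg = !(X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
              || !cur[idx3(X, Y, Z, nx, ny)];
            if (bg) cand.push_back(i);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        fill_neighbourhood(cur, x, y, z, nx, ny, nz, nb);
        int nn = n_fg_neighbours26(nb);
        if (nn <= 1) continue;              // endpoint or isolated: keep
        if (!is_simple(nb)) continue;
        cur[i] = false;
        changed = true;
      }
    }
  }
  return cur;
}

// Connected-component labels; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector vol, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(vol.size(), 0);
  int ncomp = 0;
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && s != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }
  for (int start = 0; start < (int)vol.size(); ++start) {
    if (!vol[start] || lab[start]) continue;
    ++ncomp;
    std::queue<int> q; q.push(start); lab[start] = ncomp;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        int X = x + offs[k][0], Y = y + offs[k][1], Z = z + offs[k][2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        int j = idx3(X, Y, Z, nx, ny);
        if (!vol[j] || lab[j]) continue;
        lab[j] = ncomp; q.push(j);
      }
    }
  }
  return lab;
}

// 1-D threshold-free cluster enhancement on a non-negative statistic vector.
// tfce(s) = sum over thresholds h = dh, 2dh, ... <= stat(s) of e(h,s)^E h^H dh,
// where e(h,s) is the length of the contiguous run of entries >= h containing s.
// [[Rcpp::export]]
NumericVector tfce1d_cpp(NumericVector stat, double E, double H, double dh) {
  int n = stat.size();
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || dh <= 0.0) return out;
  int nsteps = (int)std::floor(mx / dh + 1e-12);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    double inc = std::pow(h, H) * dh;
    int i = 0;
    while (i < n) {
      if (stat[i] >= h) {
        int j = i;
        while (j < n && stat[j] >= h) ++j;
        double e = std::pow((double)(j - i), E) * inc;
        for (int k = i; k < j; ++k) out[k] += e;
        i = j;
      } else ++i;
    }
  }
  return out;
}

// Index (1-based) of the nearest reference point for each query point,
// plus the distance. Brute force; refs are curve samples (small).
// [[Rcpp::export]]
List nearest_ref_cpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = 0;
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
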