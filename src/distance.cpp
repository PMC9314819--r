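// Distance computations on 3D label volumes.
//
// Conventions: arrays are column-major with dim = c(nz, ny, nx), z being the
// adaxial -> abaxial depth axis. Linear index (0-based): i = z + nz*(y + ny*x).
// All distances are returned in voxel units; callers scale by the voxel pitch.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Move {
  int dz, dy, dx;
  double w;                 // Euclidean step length (voxels)
  std::vector<int> steps;   // intermediate (dz,dy,dx) offsets for blocking checks
};

int igcd(int a, int b) { while (b) { int t = a % b; a = b; b = t; } return a; }

// Primitive integer displacement vectors within a (2k+1)^3 neighborhood.
// k = 1 gives the classic 26-neighbor quasi-Euclidean (1, sqrt2, sqrt3) set;
// k = 2/3 add knight-type moves that shrink the free-space metric error.
std::vector<Move> build_moves(int order) {
  std::vector<Move> mv;
  for (int dz = -order; dz <= order; ++dz)
    for (int dy = -order; dy <= order; ++dy)
      for (int dx = -order; dx <= order; ++dx) {
        if (!dz && !dy && !dx) continue;
        int g = igcd(igcd(std::abs(dz), std::abs(dy)), std::abs(dx));
        if (g != 1) continue;  // non-primitive vectors never shorten a path
        Move m;
        m.dz = dz; m.dy = dy; m.dx = dx;
        m.w = std::sqrt((double)(dz * dz + dy * dy + dx * dx));
        int n = std::max(std::abs(dz), std::max(std::abs(dy), std::abs(dx)));
        for (int i = 1; i < n; ++i) {
          double t = (double)i / n;
          m.steps.push_back((int)std::lround(t * dz));
          m.steps.push_back((int)std::lround(t * dy));
          m.steps.push_back((int)std::lround(t * dx));
        }
        mv.push_back(m);
      }
  return mv;
}

}  // namespace

// Geodesic (within-domain) distance from a set of seed voxels, by Dijkstra
// propagation over the move set above. `open` marks traversable voxels.
// Unreachable open voxels keep +Inf.
// [[Rcpp::export]]
NumericVector cpp_geodesic(IntegerVector dim, LogicalVector open,
                           IntegerVector seeds, int nb_order) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if ((R_xlen_t)open.size() != n) stop("open mask does not match dim");
  if (nb_order < 1 || nb_order > 4) stop("nb_order must be between 1 and 4");
  NumericVector dist(n, R_PosInf);
  std::vector<Move> mv = build_moves(nb_order);

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (R_xlen_t k = 0; k < seeds.size(); ++k) {
    R_xlen_t s = seeds[k];
    if (s < 0 || s >= n) stop("seed index out of range");
    if (!open[s]) stop("seed voxel %d is not inside the open domain", (int)s + 1);
    dist[s] = 0.0;
    pq.push(QE(0.0, s));
  }

  while (!pq.empty()) {
    double d = pq.top().first;
    R_xlen_t v = pq.top().second;
    pq.pop();
    if (d > dist[v]) continue;
    int x = (int)(v / ((R_xlen_t)nz * ny));
    R_xlen_t rem = v - (R_xlen_t)x * nz * ny;
    int y = (int)(rem / nz);
    int z = (int)(rem - (R_xlen_t)y * nz);
    for (size_t j = 0; j < mv.size(); ++j) {
      const Move& m = mv[j];
      int z2 = z + m.dz, y2 = y + m.dy, x2 = x + m.dx;
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t v2 = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (!open[v2]) continue;
      bool blocked = false;
      for (size_t s2 = 0; s2 < m.steps.size(); s2 += 3) {
        R_xlen_t vi = (z + m.steps[s2]) +
          (R_xlen_t)nz * ((y + m.steps[s2 + 1]) +
                          (R_xlen_t)ny * (x + m.steps[s2 + 2]));
        if (!open[vi]) { blocked = true; break; }
      }
      if (blocked) continue;
      double nd = d + m.w;
      if (nd < dist[v2]) {
        dist[v2] = nd;
        pq.push(QE(nd, v2));
      }
    }
  }
  return dist;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared-distance transform.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -1e30;
  zb[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

}  // namespace

// Exact Euclidean distance (voxels) from every voxel to the nearest seed
// voxel, by the separable squared-distance transform.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector dim, LogicalVector seed) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if ((R_xlen_t)seed.size() != n) stop("seed mask does not match dim");
  const double INF = 1e30;
  std::vector<double> g(n);
  bool any = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    g[i] = seed[i] ? 0.0 : INF;
    any = any || seed[i];
  }
  if (!any) stop("distance transform requires at least one seed voxel");

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: along z (stride 1)
  for (R_xlen_t x = 0; x < nx; ++x)
    for (R_xlen_t y = 0; y < ny; ++y) {
      R_xlen_t base = nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = g[base + z];
      dt1d(f, d, nz, v, zb);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // pass 2: along y (stride nz)
  for (R_xlen_t x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nz * y];
      dt1d(f, d, ny, v, zb);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass 3: along x (stride nz*ny)
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = g[base + (R_xlen_t)nz * ny * x];
      dt1d(f, d, nx, v, zb);
      for (int x = 0; x < nx; ++x) g[base + (R_xlen_t)nz * ny * x] = d[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// 4-connected component labelling of a 2D mask (used for paradermal
// sections); labels are 1..k in scan order, 0 outside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = cur;
      while (!stack.empty()) {
        int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        const int dr[4] = {1, -1, 0, 0};
        const int dc[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = cur;
            stack.push_back(std::make_pair(r2, c2));
          }
        }
      }
    }
  return lab;
}
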