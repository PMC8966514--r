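#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Arrays are passed flattened with dims (ny, nx, nz); linear index
// i = iy + ny * (ix + nx * iz).  A single-slice array (nz = 1) makes every
// 3D kernel a 2D one (26-connectivity degenerates to 8-connectivity).

namespace {

struct Dims {
  int ny, nx, nz;
  inline int idx(int iy, int ix, int iz) const { return iy + ny * (ix + nx * iz); }
  inline int n() const { return ny * nx * nz; }
};

// Neighbor offsets for 6 (face), 18 (face+edge) or 26 (full) connectivity.
static std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int m = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6  && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dy, dx, dz});
      }
  return off;
}

} // namespace

// Connected-component labeling of a binary mask. Returns integer labels,
// 0 = background, components numbered 1..K in scan order (deterministic).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, int ny, int nx, int nz,
                         int connectivity) {
  Dims d{ny, nx, nz};
  auto off = neighbor_offsets(connectivity);
  IntegerVector lab(d.n(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < d.n(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pz = p / (ny * nx), r = p % (ny * nx);
      int px = r / ny, py = r % ny;
      for (auto &o : off) {
        int qy = py + o[0], qx = px + o[1], qz = pz + o[2];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || qz < 0 || qz >= nz)
          continue;
        int q = d.idx(qy, qx, qz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared-distance transform with sample
// spacing w (parabola lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& out,
                 int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = 1e30;
  double w2 = w * w;
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * w;
    out[q] = dq * dq + f[v[k]];
  }
}

} // namespace

// Exact Euclidean distance of each foreground voxel to the nearest
// background voxel, with anisotropic spacings (wy, wx, wz). The array
// border is not treated as background.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, int ny, int nx, int nz,
                    double wy, double wx, double wz) {
  Dims d{ny, nx, nz};
  const double INF = 1e30;
  NumericVector g(d.n());
  for (int i = 0; i < d.n(); ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), o(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[d.idx(iy, ix, iz)];
      dt1d(f, o, ny, wy, v, z);
      for (int iy = 0; iy < ny; ++iy) g[d.idx(iy, ix, iz)] = o[iy];
    }
  // pass along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[d.idx(iy, ix, iz)];
      dt1d(f, o, nx, wx, v, z);
      for (int ix = 0; ix < nx; ++ix) g[d.idx(iy, ix, iz)] = o[ix];
    }
  // pass along z
  if (nz > 1)
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy) {
        for (int iz = 0; iz < nz; ++iz) f[iz] = g[d.idx(iy, ix, iz)];
        dt1d(f, o, nz, wz, v, z);
        for (int iz = 0; iz < nz; ++iz) g[d.idx(iy, ix, iz)] = o[iz];
      }

  for (int i = 0; i < d.n(); ++i)
    g[i] = g[i] >= 1e29 ? R_PosInf : std::sqrt(g[i]);
  return g;
}

// Grayscale reconstruction by dilation of `marker` under `mask_img`
// (marker <= mask_img pointwise), restricted to `fg`. Hybrid raster
// forward/backward sweeps iterated to stability.
// [[Rcpp::export(name = ".reconstruct_dilation")]]
NumericVector reconstruct_dilation(NumericVector marker, NumericVector mask_img,
                                   LogicalVector fg, int ny, int nx, int nz,
                                   int connectivity) {
  Dims d{ny, nx, nz};
  auto off = neighbor_offsets(connectivity);
  NumericVector rec = clone(marker);
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10000) {
    changed = false;
    // forward then backward sweep
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int s = 0; s < d.n(); ++s) {
        int i = sweep == 0 ? s : d.n() - 1 - s;
        if (!fg[i]) continue;
        int pz = i / (ny * nx), r = i % (ny * nx);
        int px = r / ny, py = r % ny;
        double m = rec[i];
        for (auto &o : off) {
          int qy = py + o[0], qx = px + o[1], qz = pz + o[2];
          if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || qz < 0 || qz >= nz)
            continue;
          int q = d.idx(qy, qx, qz);
          if (fg[q] && rec[q] > m) m = rec[q];
        }
        if (m > mask_img[i]) m = mask_img[i];
        if (m > rec[i]) { rec[i] = m; changed = true; }
      }
    }
  }
  return rec;
}

// Regional maxima (plateau-aware) of `img` restricted to `fg`, labeled
// 1..K in scan order. A plateau is a maximum iff no neighbor is higher.
// [[Rcpp::export(name = ".regional_maxima")]]
IntegerVector regional_maxima(NumericVector img, LogicalVector fg,
                              int ny, int nx, int nz, int connectivity) {
  Dims d{ny, nx, nz};
  auto off = neighbor_offsets(connectivity);
  const double tol = 1e-9;
  // -1 unvisited, 0 not-a-maximum, k>0 maximum label
  IntegerVector lab(d.n(), -1);
  int next = 0;
  std::vector<int> comp, stack;
  for (int i = 0; i < d.n(); ++i) {
    if (!fg[i]) { lab[i] = 0; continue; }
    if (lab[i] != -1) continue;
    double val = img[i];
    comp.clear(); stack.clear();
    stack.push_back(i);
    lab[i] = -2; // in-progress
    comp.push_back(i);
    bool is_max = true;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pz = p / (ny * nx), r = p % (ny * nx);
      int px = r / ny, py = r % ny;
      for (auto &o : off) {
        int qy = py + o[0], qx = px + o[1], qz = pz + o[2];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || qz < 0 || qz >= nz)
          continue;
        int q = d.idx(qy, qx, qz);
        if (!fg[q]) continue;
        if (img[q] > val + tol) { is_max = false; continue; }
        if (img[q] >= val - tol && lab[q] == -1) {
          lab[q] = -2; comp.push_back(q); stack.push_back(q);
        }
      }
    }
    int assign = is_max ? ++next : 0;
    for (int p : comp) lab[p] = assign;
  }
  return lab;
}

namespace {
struct QEntry {
  double h;       // flooding height (larger floods first)
  int64_t order;  // insertion counter: FIFO among equal heights
  int idx;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.h != b.h) return a.h < b.h;     // max-heap on height
    return a.order > b.order;             // earlier insertion first
  }
};
} // namespace

// Marker-controlled watershed flooding of the height field `ht`
// (descending from the marker peaks), restricted to foreground `fg`.
// Voxels where two labels meet become ridge (0). Deterministic.
// [[Rcpp::export(name = ".marker_watershed")]]
IntegerVector marker_watershed(NumericVector ht, IntegerVector markers,
                               LogicalVector fg, int ny, int nx, int nz,
                               int connectivity) {
  Dims d{ny, nx, nz};
  auto off = neighbor_offsets(connectivity);
  const int UNSEEN = -1, RIDGE = 0;
  IntegerVector lab(d.n());
  std::vector<bool> queued(d.n(), false);
  for (int i = 0; i < d.n(); ++i) lab[i] = fg[i] ? UNSEEN : RIDGE;

  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  int64_t counter = 0;
  for (int i = 0; i < d.n(); ++i)
    if (fg[i] && markers[i] > 0) {
      lab[i] = markers[i];
      pq.push({ht[i], counter++, i});
      queued[i] = true;
    }

  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int p = e.idx;
    int pz = p / (ny * nx), r = p % (ny * nx);
    int px = r / ny, py = r % ny;

    if (lab[p] == UNSEEN) {
      // decide label from already-labeled neighbors
      int found = 0; bool conflict = false;
      for (auto &o : off) {
        int qy = py + o[0], qx = px + o[1], qz = pz + o[2];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || qz < 0 || qz >= nz)
          continue;
        int q = d.idx(qy, qx, qz);
        if (fg[q] && lab[q] > 0) {
          if (found == 0) found = lab[q];
          else if (lab[q] != found) conflict = true;
        }
      }
      lab[p] = conflict || found == 0 ? RIDGE : found;
    }
    if (lab[p] == RIDGE) continue;
    for (auto &o : off) {
      int qy = py + o[0], qx = px + o[1], qz = pz + o[2];
      if (qy < 0 || qy >= ny || qx < 0 || qx >= nx || qz < 0 || qz >= nz)
        continue;
      int q = d.idx(qy, qx, qz);
      if (fg[q] && lab[q] == UNSEEN && !queued[q]) {
        pq.push({ht[q], counter++, q});
        queued[q] = true;
      }
    }
  }
  // any foreground voxel never reached (no marker in its component)
  for (int i = 0; i < d.n(); ++i)
    if (fg[i] && lab[i] == UNSEEN) lab[i] = RIDGE;
  return lab;
}

namespace {
// uniform grid over points for radius queries
struct PointGrid {
  double x0, y0, cell;
  int ncx, ncy;
  std::unordered_map<int64_t, std::vector<int>> cells;
  inline int64_t key(int cx, int cy) const {
    return (int64_t)cx * 2000003LL + cy;
  }
  void build(const NumericVector& x, const NumericVector& y, double cell_) {
    cell = cell_;
    x0 = R_PosInf; y0 = R_PosInf;
    for (int i = 0; i < x.size(); ++i) {
      if (x[i] < x0) x0 = x[i];
      if (y[i] < y0) y0 = y[i];
    }
    for (int i = 0; i < x.size(); ++i) {
      int cx = (int)std::floor((x[i] - x0) / cell);
      int cy = (int)std::floor((y[i] - y0) / cell);
      cells[key(cx, cy)].push_back(i);
    }
  }
};
} // namespace

// DBSCAN over 2D points; returns cluster ids (0 = noise), clusters
// numbered in order of discovery from the lowest-index core point.
// The query point itself counts toward minPts.
// [[Rcpp::export(name = ".dbscan2d")]]
IntegerVector dbscan2d(NumericVector x, NumericVector y,
                       double eps, int minPts) {
  int n = x.size();
  IntegerVector cl(n, 0);
  if (n == 0) return cl;
  PointGrid g;
  g.build(x, y, eps);
  double eps2 = eps * eps;

  auto neighbors = [&](int i, std::vector<int>& out) {
    out.clear();
    int cx = (int)std::floor((x[i] - g.x0) / g.cell);
    int cy = (int)std::floor((y[i] - g.y0) / g.cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = g.cells.find(g.key(cx + dx, cy + dy));
        if (it == g.cells.end()) continue;
        for (int j : it->second) {
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
  };

  std::vector<bool> visited(n, false);
  std::vector<int> nb, nb2, seeds;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    neighbors(i, nb);
    if ((int)nb.size() < minPts) continue;  // noise (may be claimed later)
    ++next;
    cl[i] = next;
    seeds.assign(nb.begin(), nb.end());
    for (size_t k = 0; k < seeds.size(); ++k) {
      int j = seeds[k];
      if (cl[j] == 0) cl[j] = next;      // border or previously-noise point
      if (visited[j]) continue;
      visited[j] = true;
      neighbors(j, nb2);
      if ((int)nb2.size() >= minPts)
        seeds.insert(seeds.end(), nb2.begin(), nb2.end());
    }
  }
  return cl;
}

// Nearest-neighbor distance of each 2D point to any other point,
// grid-accelerated ring search.
// [[Rcpp::export(name = ".nnd2d")]]
NumericVector nnd2d(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n, R_PosInf);
  if (n < 2) return out;
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y);
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = span > 0 ? span / std::max(1.0, std::ceil(std::sqrt((double)n)))
                         : 1.0;
  PointGrid g;
  g.build(x, y, cell);
  int ncmax = (int)std::ceil(span / cell) + 2;

  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - g.x0) / cell);
    int cy = (int)std::floor((y[i] - g.y0) / cell);
    double best = R_PosInf;
    for (int ring = 0; ring <= ncmax; ++ring) {
      // distance from point to nearest face of the unexplored region
      if (ring > 0) {
        double bound = (ring - 1) * cell;  // conservative lower bound
        if (best <= bound * bound) break;
      }
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          auto it = g.cells.find(g.key(cx + dx, cy + dy));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = x[j] - x[i], ddy = y[j] - y[i];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) best = d2;
          }
        }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
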