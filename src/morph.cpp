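#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// (z, y, x) column-major arrays: idx = z + nz * (y + ny * x)

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with spacing h;
// INF sources (no background anywhere on the line) are skipped
void dt1d(const std::vector<double> &f, std::vector<double> &d, int n, double h) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double dd = qq - (double)v[k] * h;
    d[q] = dd * dd + f[v[k]];
  }
}

} // namespace

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel (anisotropic spacing); background voxels get 0.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  std::vector<double> d(nvox);
  for (long i = 0; i < nvox; ++i) d[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, out;
  // axis z
  f.resize(nz); out.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      long base = (long)nz * (y + (long)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = d[base + z];
      dt1d(f, out, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) d[base + z] = out[z];
    }
  // axis y
  f.resize(ny); out.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      long base = z + (long)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (long)nz * y];
      dt1d(f, out, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (long)nz * y] = out[y];
    }
  // axis x
  f.resize(nx); out.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      long base = z + (long)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = d[base + (long)nz * ny * x];
      dt1d(f, out, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) d[base + (long)nz * ny * x] = out[x];
    }

  NumericVector res(nvox);
  for (long i = 0; i < nvox; ++i) res[i] = std::sqrt(d[i]);
  res.attr("dim") = dim;
  return res;
}

// indices (1-based) of voxels that are >= all 26 neighbours and > threshold
// [[Rcpp::export(name = ".local_maxima3d_cpp")]]
IntegerVector local_maxima3d_cpp(NumericVector a, IntegerVector dim, double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long idx = z + (long)nz * (y + (long)ny * x);
        double v = a[idx];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (a[zz + (long)nz * (yy + (long)ny * xx)] > v) ismax = false;
            }
        if (ismax) hits.push_back((int)(idx + 1));
      }
  return IntegerVector(hits.begin(), hits.end());
}

namespace {
struct QE {
  double cost;
  long order;
  long idx;
  int label;
};
struct QEComp {
  bool operator()(const QE &a, const QE &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.order > b.order; // FIFO among equal costs -> deterministic
  }
};
} // namespace

// marker-controlled watershed: flood `cost` (lower first) from seeds,
// restricted to mask, 26-connectivity; ties broken by insertion order
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector cost, IntegerVector dim,
                            IntegerVector mask, IntegerVector seed_idx1) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dim;
  std::priority_queue<QE, std::vector<QE>, QEComp> pq;
  long order = 0;
  for (int s = 0; s < seed_idx1.size(); ++s) {
    long idx = (long)seed_idx1[s] - 1;
    if (!mask[idx]) continue; // caller warns about dropped seeds
    pq.push(QE{cost[idx], order++, idx, s + 1});
  }
  while (!pq.empty()) {
    QE e = pq.top();
    pq.pop();
    if (labels[e.idx]) continue;
    labels[e.idx] = e.label;
    int z = (int)(e.idx % nz);
    long rest = e.idx / nz;
    int y = (int)(rest % ny), x = (int)(rest / ny);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          long nidx = zz + (long)nz * (yy + (long)ny * xx);
          if (!mask[nidx] || labels[nidx]) continue;
          pq.push(QE{cost[nidx], order++, nidx, e.label});
        }
  }
  return labels;
}

// 26-connected component labelling of a binary mask
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dim;
  int cur = 0;
  std::vector<long> stack;
  for (long i = 0; i < nvox; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++cur;
    stack.push_back(i);
    labels[i] = cur;
    while (!stack.empty()) {
      long idx = stack.back();
      stack.pop_back();
      int z = (int)(idx % nz);
      long rest = idx / nz;
      int y = (int)(rest % ny), x = (int)(rest / ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            long nidx = zz + (long)nz * (yy + (long)ny * xx);
            if (mask[nidx] && !labels[nidx]) {
              labels[nidx] = cur;
              stack.push_back(nidx);
            }
          }
    }
  }
  return labels;
}

// Dijkstra shortest path on the 26-connected voxel grid restricted to mask;
// edge weight = euclidean step length (um) * mean of node costs.
// Returns 1-based voxel indices from src to dst, or empty if unreachable.
// [[Rcpp::export(name = ".dijkstra_path_cpp")]]
IntegerVector dijkstra_path_cpp(NumericVector cost, IntegerVector dim,
                                NumericVector spacing, IntegerVector mask,
                                int src1, int dst1) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  long src = src1 - 1, dst = dst1 - 1;
  std::vector<double> dist(nvox, INF);
  std::vector<long> prev(nvox, -1);
  typedef std::pair<double, long> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  dist[src] = 0.0;
  pq.push(P(0.0, src));
  while (!pq.empty()) {
    P top = pq.top();
    pq.pop();
    long u = top.second;
    if (top.first > dist[u]) continue;
    if (u == dst) break;
    int z = (int)(u % nz);
    long rest = u / nz;
    int y = (int)(rest % ny), x = (int)(rest / ny);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          long v = zz + (long)nz * (yy + (long)ny * xx);
          if (!mask[v]) continue;
          double sz = dz * spacing[0], sy = dy * spacing[1], sx = dx * spacing[2];
          double step = std::sqrt(sz * sz + sy * sy + sx * sx);
          double w = step * 0.5 * (cost[u] + cost[v]);
          double nd = dist[u] + w;
          if (nd < dist[v]) {
            dist[v] = nd;
            prev[v] = u;
            pq.push(P(nd, v));
          }
        }
  }
  if (dist[dst] == INF) return IntegerVector(0);
  std::vector<int> path;
  for (long v = dst; v != -1; v = prev[v]) path.push_back((int)(v + 1));
  std::reverse(path.begin(), path.end());
  return IntegerVector(path.begin(), path.end());
}
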