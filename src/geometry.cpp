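#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// (z, y, x) column-major arrays; voxel center of 0-based index v at
// (v + 0.5) * spacing in um.

// Stamp balls of radius radius[i] + extra around each centerline sample and
// keep, per voxel, the distance to the nearest sample together with that
// sample's arc length and tube radius. Voxels never touched keep dist = Inf.
// [[Rcpp::export(name = ".paint_tube_cpp")]]
List paint_tube_cpp(IntegerVector dim, NumericVector spacing, NumericMatrix pts,
                    NumericVector arclen, NumericVector radius, double extra) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  NumericVector dist(nvox, R_PosInf), sarc(nvox, NA_REAL), srad(nvox, NA_REAL);
  dist.attr("dim") = dim;
  sarc.attr("dim") = dim;
  srad.attr("dim") = dim;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double pz = pts(i, 0), py = pts(i, 1), px = pts(i, 2);
    double r = radius[i] + extra;
    int z0 = std::max(0, (int)std::floor((pz - r) / spacing[0] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + r) / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((py - r) / spacing[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((py + r) / spacing[1] - 0.5));
    int x0 = std::max(0, (int)std::floor((px - r) / spacing[2] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((px + r) / spacing[2] - 0.5));
    double r2 = r * r;
    for (int x = x0; x <= x1; ++x) {
      double dx = (x + 0.5) * spacing[2] - px, dx2 = dx * dx;
      if (dx2 > r2) continue;
      for (int y = y0; y <= y1; ++y) {
        double dy = (y + 0.5) * spacing[1] - py, dyx2 = dx2 + dy * dy;
        if (dyx2 > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double dz = (z + 0.5) * spacing[0] - pz;
          double d2 = dyx2 + dz * dz;
          if (d2 > r2) continue;
          long idx = z + (long)nz * (y + (long)ny * x);
          double d = std::sqrt(d2);
          if (d < dist[idx]) {
            dist[idx] = d;
            sarc[idx] = arclen[i];
            srad[idx] = radius[i];
          }
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["arclen"] = sarc, _["radius"] = srad);
}

// Rasterize ellipsoids into an integer label volume. `rot` holds, per
// nucleus, the 3x3 rotation with rows = principal axis directions (world
// z,y,x components), flattened row-major into 9 columns.
// [[Rcpp::export(name = ".paint_ellipsoids_cpp")]]
IntegerVector paint_ellipsoids_cpp(IntegerVector dim, NumericVector spacing,
                                   NumericMatrix centers, NumericMatrix axes,
                                   NumericMatrix rot) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dim;
  int n = centers.nrow();
  for (int i = 0; i < n; ++i) {
    double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    double rmax = std::max(axes(i, 0), std::max(axes(i, 1), axes(i, 2)));
    int z0 = std::max(0, (int)std::floor((cz - rmax) / spacing[0] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + rmax) / spacing[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - rmax) / spacing[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + rmax) / spacing[1] - 0.5));
    int x0 = std::max(0, (int)std::floor((cx - rmax) / spacing[2] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + rmax) / spacing[2] - 0.5));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double pz = (z + 0.5) * spacing[0] - cz;
          double py = (y + 0.5) * spacing[1] - cy;
          double px = (x + 0.5) * spacing[2] - cx;
          double u0 = (rot(i, 0) * pz + rot(i, 1) * py + rot(i, 2) * px) / axes(i, 0);
          double u1 = (rot(i, 3) * pz + rot(i, 4) * py + rot(i, 5) * px) / axes(i, 1);
          double u2 = (rot(i, 6) * pz + rot(i, 7) * py + rot(i, 8) * px) / axes(i, 2);
          if (u0 * u0 + u1 * u1 + u2 * u2 <= 1.0) {
            long idx = z + (long)nz * (y + (long)ny * x);
            if (labels[idx] == 0) labels[idx] = i + 1;
          }
        }
  }
  return labels;
}
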