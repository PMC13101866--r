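#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Arrays are R 3D arrays in (z, y, x) order, column-major:
// linear index = z + nz * (y + ny * x).

namespace {

std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-(double)(i * i) / s2);
    sum += k[i + r];
  }
  for (double &v : k) v /= sum;
  return k;
}

// second derivative of the (discretely normalized) Gaussian; sums to zero
std::vector<double> gauss_d2_kernel(double sigma) {
  std::vector<double> g = gauss_kernel(sigma);
  int r = ((int)g.size() - 1) / 2;
  std::vector<double> k(g.size());
  double s2 = sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = g[i + r] * ((double)(i * i) - s2) / (s2 * s2);
    sum += k[i + r];
  }
  double corr = sum / (double)k.size();
  for (double &v : k) v -= corr;  // zero response on constants
  return k;
}

// in-place separable convolution along one axis with replicate boundary
void conv_axis(std::vector<double> &a, int nz, int ny, int nx, int axis,
               const std::vector<double> &ker) {
  int r = ((int)ker.size() - 1) / 2;
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nz : (long)nz * ny;
  std::vector<double> line(n), out(n);
  long n_outer1, n_outer2, s1, s2;
  if (axis == 0) {
    n_outer1 = ny; s1 = (long)nz;
    n_outer2 = nx; s2 = (long)nz * ny;
  } else if (axis == 1) {
    n_outer1 = nz; s1 = 1L;
    n_outer2 = nx; s2 = (long)nz * ny;
  } else {
    n_outer1 = nz; s1 = 1L;
    n_outer2 = ny; s2 = (long)nz;
  }
  for (long o2 = 0; o2 < n_outer2; ++o2) {
    for (long o1 = 0; o1 < n_outer1; ++o1) {
      long base = o1 * s1 + o2 * s2;
      for (int i = 0; i < n; ++i) line[i] = a[base + (long)i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          acc += ker[j + r] * line[p];
        }
        out[i] = acc;
      }
      for (int i = 0; i < n; ++i) a[base + (long)i * stride] = out[i];
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".gaussian_blur3d_cpp")]]
NumericVector gaussian_blur3d_cpp(NumericVector img, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(img.begin(), img.end());
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma_vox[ax] > 1e-8) conv_axis(a, nz, ny, nx, ax, gauss_kernel(sigma_vox[ax]));
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Scale-normalized negated Laplacian of Gaussian:
//   resp = -sigma_um^2 * sum_i d2/dxi^2 [G * I]   (physical-unit Laplacian)
// so that bright blobs give positive peaks comparable across scales.
// [[Rcpp::export(name = ".log3d_cpp")]]
NumericVector log3d_cpp(NumericVector img, IntegerVector dim,
                        NumericVector sigma_vox, NumericVector spacing,
                        double sigma_um) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long nvox = (long)nz * ny * nx;
  std::vector<double> acc(nvox, 0.0);
  for (int d2ax = 0; d2ax < 3; ++d2ax) {
    std::vector<double> a(img.begin(), img.end());
    for (int ax = 0; ax < 3; ++ax) {
      std::vector<double> ker = (ax == d2ax) ? gauss_d2_kernel(sigma_vox[ax])
                                             : gauss_kernel(sigma_vox[ax]);
      conv_axis(a, nz, ny, nx, ax, ker);
    }
    double sc = 1.0 / (spacing[d2ax] * spacing[d2ax]);
    for (long i = 0; i < nvox; ++i) acc[i] += a[i] * sc;
  }
  double norm = -sigma_um * sigma_um;
  NumericVector out(nvox);
  for (long i = 0; i < nvox; ++i) out[i] = norm * acc[i];
  out.attr("dim") = dim;
  return out;
}

// trilinear sampling at continuous voxel coordinates (0-based voxel centers);
// points outside the [0, dim-1] box sample as NA
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector img, IntegerVector dim,
                            NumericMatrix pts_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = pts_vox.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z = pts_vox(i, 0), y = pts_vox(i, 1), x = pts_vox(i, 2);
    if (!(z >= 0 && z <= nz - 1 && y >= 0 && y <= ny - 1 && x >= 0 && x <= nx - 1)) {
      out[i] = NA_REAL;
      continue;
    }
    int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
        x1 = std::min(x0 + 1, nx - 1);
    double fz = z - z0, fy = y - y0, fx = x - x0;
    double v = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
          if (w == 0.0) continue;
          long idx = (long)(dz ? z1 : z0) +
                     (long)nz * ((dy ? y1 : y0) + (long)ny * (dx ? x1 : x0));
          v += w * img[idx];
        }
    out[i] = v;
  }
  return out;
}
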