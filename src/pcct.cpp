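#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear sample of img (ny x nx, column-major) at fractional pixel
// coordinates (py, px), 0-based. Outside the grid the image is zero.
static inline double bilin(const double *img, const int ny, const int nx,
                           const double py, const double px) {
  if (py <= -1.0 || px <= -1.0 || py >= (double)ny || px >= (double)nx)
    return 0.0;
  int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  double fy = py - y0, fx = px - x0;
  double v = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    int y = y0 + dy;
    if (y < 0 || y >= ny) continue;
    double wy = dy ? fy : 1.0 - fy;
    for (int dx = 0; dx <= 1; ++dx) {
      int x = x0 + dx;
      if (x < 0 || x >= nx) continue;
      double wx = dx ? fx : 1.0 - fx;
      v += wy * wx * img[y + (R_xlen_t)ny * x];
    }
  }
  return v;
}

// Parallel-beam Radon transform of a single slice.
// slice: ny x nx image, physical pixel pitch `pitch` (um), centred on the
// rotation axis. angles in radians; det: detector coordinates s (um)
// relative to the rotation axis. Integration step t_step (um) on a grid
// symmetric about t = 0 so that p(theta+pi, -s) == p(theta, s) exactly.
// Returns an n_angles x n_det matrix of line integrals in um * value.
// [[Rcpp::export]]
NumericMatrix cpp_radon(const NumericMatrix &slice, const NumericVector &angles,
                        const NumericVector &det, const double pitch,
                        const double t_step) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int nA = angles.size(), nD = det.size();
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1);
  const double half_diag =
      0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * pitch;
  const int K = (int)std::ceil(half_diag / t_step);
  NumericMatrix out(nA, nD);
  const double *img = slice.begin();
  for (int a = 0; a < nA; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int j = 0; j < nD; ++j) {
      const double x0 = det[j] * c, y0 = det[j] * s;
      double acc = 0.0;
      for (int k = -K; k <= K; ++k) {
        const double t = k * t_step;
        const double x = x0 - t * s, y = y0 + t * c;
        acc += bilin(img, ny, nx, y / pitch + cy, x / pitch + cx);
      }
      out(a, j) = acc * t_step;
    }
  }
  return out;
}

// Backprojection of a filtered sinogram (n_angles x n_det) onto an
// ny x nx grid with pixel pitch `pitch`, linear interpolation along the
// detector. det gives the s coordinate (um) of each detector column.
// The angular weight (pi / n_angles) is applied by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix &sino,
                              const NumericVector &angles,
                              const NumericVector &det, const double pitch,
                              const int ny, const int nx) {
  const int nA = sino.nrow(), nD = sino.ncol();
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1);
  const double s0 = det[0];
  const double ds = nD > 1 ? (det[1] - det[0]) : pitch;
  NumericMatrix out(ny, nx);
  for (int a = 0; a < nA; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int x = 0; x < nx; ++x) {
      const double xc = (x - cx) * pitch;
      for (int y = 0; y < ny; ++y) {
        const double yc = (y - cy) * pitch;
        const double u = (xc * c + yc * s - s0) / ds;
        if (u <= -1.0 || u >= (double)nD) continue;
        int j0 = (int)std::floor(u);
        const double f = u - j0;
        double v = 0.0;
        if (j0 >= 0 && j0 < nD) v += (1.0 - f) * sino(a, j0);
        if (j0 + 1 >= 0 && j0 + 1 < nD) v += f * sino(a, j0 + 1);
        out(y, x) += v;
      }
    }
  }
  return out;
}

// 6-connected component labelling of a 3D mask stored column-major with
// dims (nz, ny, nx). Returns integer labels (0 = background), labelled in
// first-encounter order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector &mask, const int nz, const int ny,
                          const int nx) {
  IntegerVector lab(mask.size(), 0);
  const R_xlen_t n = mask.size();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / sx);
      const R_xlen_t nb[6] = {v - 1, v + 1, v - sy, v + sy, v - sx, v + sx};
      const bool ok[6] = {z > 0, z < nz - 1, y > 0, y < ny - 1,
                          x > 0, x < nx - 1};
      for (int k = 0; k < 6; ++k) {
        if (!ok[k]) continue;
        R_xlen_t w = nb[k];
        if (mask[w] && !lab[w]) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
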