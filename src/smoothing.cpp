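#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Anatomically constrained smoothing kernels. `data` is (nvox x nt) so 4D
// series reuse the per-voxel weight computation across frames.

namespace {

inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

}  // namespace

// Gaussian smoothing restricted to voxels sharing the same layer label.
// layers == 0 marks voxels outside the layer masks: they are copied through
// untouched and never contribute weight. With no_kissing, contributions are
// further restricted to voxels reachable from the centre by a 26-connected
// path through same-layer voxels inside the truncation window, so that
// spatial proximity across a CSF gap (kissing gyri) never leaks signal.
// [[Rcpp::export]]
NumericMatrix layer_smooth_cpp(NumericMatrix data, IntegerVector layers,
                               IntegerVector dim, NumericVector voxdim,
                               double sigma, double trunc, bool no_kissing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const int nt = data.ncol();
  const double dx = voxdim[0], dy = voxdim[1], dz = voxdim[2];
  const double rad = trunc * sigma;
  const int rx = (int)std::ceil(rad / dx);
  const int ry = (int)std::ceil(rad / dy);
  const int rz = nz > 1 ? (int)std::ceil(rad / dz) : 0;

  NumericMatrix out(n, nt);
  // scratch for the no-kissing reachability search (window-local)
  const int wx = 2 * rx + 1, wy = 2 * ry + 1, wz = 2 * rz + 1;
  std::vector<char> reach(wx * wy * wz);
  std::vector<int> stack;

  for (int v = 0; v < n; ++v) {
    const int lv = layers[v];
    if (lv <= 0) {
      for (int t = 0; t < nt; ++t) out(v, t) = data(v, t);
      continue;
    }
    const int x = v % nx;
    const int y = (v / nx) % ny;
    const int z = v / (nx * ny);
    const int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
    const int y0 = std::max(0, y - ry), y1 = std::min(ny - 1, y + ry);
    const int z0 = std::max(0, z - rz), z1 = std::min(nz - 1, z + rz);

    if (no_kissing) {
      std::fill(reach.begin(), reach.end(), 0);
      stack.clear();
      const int c = (x - x0) + wx * ((y - y0) + wy * (z - z0));
      reach[c] = 1;
      stack.push_back(c);
      while (!stack.empty()) {
        const int w = stack.back();
        stack.pop_back();
        const int lx = w % wx, ly = (w / wx) % wy, lz = w / (wx * wy);
        for (int cz = -1; cz <= 1; ++cz)
          for (int cy = -1; cy <= 1; ++cy)
            for (int cx = -1; cx <= 1; ++cx) {
              if (cx == 0 && cy == 0 && cz == 0) continue;
              const int ax = lx + cx, ay = ly + cy, az = lz + cz;
              if (ax < 0 || ay < 0 || az < 0) continue;
              const int gx = x0 + ax, gy = y0 + ay, gz = z0 + az;
              if (gx > x1 || gy > y1 || gz > z1) continue;
              const int wj = ax + wx * (ay + wy * az);
              if (reach[wj]) continue;
              if (layers[lin(gx, gy, gz, nx, ny)] != lv) continue;
              reach[wj] = 1;
              stack.push_back(wj);
            }
      }
    }

    double wsum = 0.0;
    std::vector<double> acc(nt, 0.0);
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          const int u = lin(xx, yy, zz, nx, ny);
          if (layers[u] != lv) continue;
          if (no_kissing) {
            const int w =
                (xx - x0) + wx * ((yy - y0) + wy * (zz - z0));
            if (!reach[w]) continue;
          }
          const double ddx = (xx - x) * dx, ddy = (yy - y) * dy,
                       ddz = (zz - z) * dz;
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 > rad * rad) continue;
          const double w8 = std::exp(-d2 / (2.0 * sigma * sigma));
          wsum += w8;
          for (int t = 0; t < nt; ++t) acc[t] += w8 * data(u, t);
        }
    for (int t = 0; t < nt; ++t) out(v, t) = acc[t] / wsum;
  }
  return out;
}

// Edge-preserving smoothing: Gaussian distance penalty times a Gaussian
// penalty on the intensity difference in an independent anatomical-contrast
// image (`grad`), scaled by `selectivity` times the local standard
// deviation of that image in the truncation window. Voxels outside `mask`
// are copied through. Returns the smoothed matrix plus a flag vector for
// voxels whose local window was intensity-flat (penalty disabled there).
// [[Rcpp::export]]
List grad_smooth_cpp(NumericMatrix data, NumericVector grad,
                     LogicalVector mask, IntegerVector dim,
                     NumericVector voxdim, double sigma, double trunc,
                     double selectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const int nt = data.ncol();
  const double dx = voxdim[0], dy = voxdim[1], dz = voxdim[2];
  const double rad = trunc * sigma;
  const int rx = (int)std::ceil(rad / dx);
  const int ry = (int)std::ceil(rad / dy);
  const int rz = nz > 1 ? (int)std::ceil(rad / dz) : 0;

  NumericMatrix out(n, nt);
  LogicalVector flat(n, false);

  for (int v = 0; v < n; ++v) {
    if (!mask[v]) {
      for (int t = 0; t < nt; ++t) out(v, t) = data(v, t);
      continue;
    }
    const int x = v % nx;
    const int y = (v / nx) % ny;
    const int z = v / (nx * ny);
    const int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
    const int y0 = std::max(0, y - ry), y1 = std::min(ny - 1, y + ry);
    const int z0 = std::max(0, z - rz), z1 = std::min(nz - 1, z + rz);

    // local scale: SD of the contrast image over mask voxels in the window
    double s1 = 0.0, s2 = 0.0;
    int cnt = 0;
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          const int u = lin(xx, yy, zz, nx, ny);
          if (!mask[u]) continue;
          s1 += grad[u];
          s2 += grad[u] * grad[u];
          ++cnt;
        }
    double sd = 0.0;
    if (cnt > 1) {
      const double m = s1 / cnt;
      const double var = s2 / cnt - m * m;
      sd = var > 0 ? std::sqrt(var) : 0.0;
    }
    const bool use_int = sd > 0;
    if (!use_int) flat[v] = true;
    const double denom = 2.0 * selectivity * selectivity * sd * sd;

    double wsum = 0.0;
    std::vector<double> acc(nt, 0.0);
    const double gv = grad[v];
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          const int u = lin(xx, yy, zz, nx, ny);
          if (!mask[u]) continue;
          const double ddx = (xx - x) * dx, ddy = (yy - y) * dy,
                       ddz = (zz - z) * dz;
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 > rad * rad) continue;
          double w = std::exp(-d2 / (2.0 * sigma * sigma));
          if (use_int) {
            const double di = grad[u] - gv;
            w *= std::exp(-(di * di) / denom);
          }
          wsum += w;
          for (int t = 0; t < nt; ++t) acc[t] += w * data(u, t);
        }
    for (int t = 0; t < nt; ++t) out(v, t) = acc[t] / wsum;
  }
  return List::create(_["out"] = out, _["flat_window"] = flat);
}
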