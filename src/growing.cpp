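#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice growing kernels. All volumes arrive as flat vectors in R's
// column-major order; indices exchanged with R are 1-based.

namespace {

struct QNode {
  double dist;
  int origin;  // 1-based linear index of the source voxel
  int idx;     // 0-based linear index of this voxel
};

struct QNodeCmp {
  // min-heap on (dist, origin): equal-length paths resolve to the
  // smallest source index, keeping nearest-border assignment deterministic
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.origin > b.origin;
  }
};

}  // namespace

// Multi-source geodesic distances on the 26-connected lattice with true
// Euclidean step costs under anisotropic voxel sizes. Sources are the
// voxels with code == source_code (distance 0); paths may only traverse
// voxels whose code appears in `allowed`.
// [[Rcpp::export]]
List grow_geodesic_cpp(IntegerVector codes, IntegerVector dim,
                       NumericVector voxdim, int source_code,
                       IntegerVector allowed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double dx = voxdim[0], dy = voxdim[1], dz = voxdim[2];

  std::vector<bool> ok(256, false);
  for (int i = 0; i < allowed.size(); ++i) {
    int a = allowed[i];
    if (a >= 0 && a < 256) ok[a] = true;
  }

  // neighbour offsets and step costs
  std::vector<int> noff;
  std::vector<double> ncost;
  std::vector<int> ndx, ndy, ndz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        ndx.push_back(cx); ndy.push_back(cy); ndz.push_back(cz);
        ncost.push_back(std::sqrt(cx * cx * dx * dx + cy * cy * dy * dy +
                                  cz * cz * dz * dz));
      }

  NumericVector dist(n, R_PosInf);
  IntegerVector origin(n, NA_INTEGER);
  std::vector<bool> done(n, false);

  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  for (int i = 0; i < n; ++i) {
    if (codes[i] == source_code) pq.push(QNode{0.0, i + 1, i});
  }

  while (!pq.empty()) {
    QNode top = pq.top();
    pq.pop();
    if (done[top.idx]) continue;
    done[top.idx] = true;
    dist[top.idx] = top.dist;
    origin[top.idx] = top.origin;
    const int x = top.idx % nx;
    const int y = (top.idx / nx) % ny;
    const int z = top.idx / (nx * ny);
    for (size_t k = 0; k < ncost.size(); ++k) {
      const int xx = x + ndx[k], yy = y + ndy[k], zz = z + ndz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int j = xx + nx * (yy + ny * zz);
      if (done[j]) continue;
      const int cj = codes[j];
      if (cj < 0 || cj >= 256 || !ok[cj]) continue;
      const double nd = top.dist + ncost[k];
      if (nd < dist[j]) {
        dist[j] = nd;  // provisional; finalized on pop
        pq.push(QNode{nd, top.origin, j});
      } else if (nd == dist[j]) {
        // same length via another source: let the heap order decide
        pq.push(QNode{nd, top.origin, j});
      }
    }
  }

  // reset provisional distances of never-finalized voxels
  for (int i = 0; i < n; ++i)
    if (!done[i]) dist[i] = R_PosInf;

  return List::create(_["dist"] = dist, _["origin"] = origin);
}

// Multi-source unit-step growing over the face-connected lattice
// (6-neighborhood; degenerates to 4 in single-slice volumes). Each voxel
// records the number of growth iterations from the nearest source and
// inherits that source's value. Growth is confined to `allowed` voxels.
// [[Rcpp::export]]
List grow_steps_cpp(LogicalVector allowed, IntegerVector dim,
                    IntegerVector sources, NumericVector source_values) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;

  IntegerVector steps(n, NA_INTEGER);
  NumericVector value(n, NA_REAL);
  IntegerVector origin(n, NA_INTEGER);

  std::queue<int> q;
  for (int i = 0; i < sources.size(); ++i) {
    const int s = sources[i] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    if (steps[s] == NA_INTEGER) {
      steps[s] = 0;
      value[s] = source_values[i];
      origin[s] = s + 1;
      q.push(s);
    }
  }

  const int offx[6] = {-1, 1, 0, 0, 0, 0};
  const int offy[6] = {0, 0, -1, 1, 0, 0};
  const int offz[6] = {0, 0, 0, 0, -1, 1};

  while (!q.empty()) {
    const int i = q.front();
    q.pop();
    const int x = i % nx;
    const int y = (i / nx) % ny;
    const int z = i / (nx * ny);
    for (int k = 0; k < 6; ++k) {
      const int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int j = xx + nx * (yy + ny * zz);
      if (!allowed[j]) continue;
      if (steps[j] != NA_INTEGER) continue;
      steps[j] = steps[i] + 1;
      value[j] = value[i];
      origin[j] = origin[i];
      q.push(j);
    }
  }

  return List::create(_["steps"] = steps, _["value"] = value,
                      _["origin"] = origin);
}

// 26-connected component labels over `mask` voxels (0 elsewhere).
// [[Rcpp::export]]
IntegerVector connected_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      const int i = q.front();
      q.pop();
      const int x = i % nx;
      const int y = (i / nx) % ny;
      const int z = i / (nx * ny);
      for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
          for (int cx = -1; cx <= 1; ++cx) {
            if (cx == 0 && cy == 0 && cz == 0) continue;
            const int xx = x + cx, yy = y + cy, zz = z + cz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            const int j = xx + nx * (yy + ny * zz);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              q.push(j);
            }
          }
    }
  }
  return lab;
}
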