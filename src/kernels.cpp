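#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D grid at continuous 0-based positions.
// vol carries a dim attribute (nx, ny, nz); pts is n x 3 (X, Y, Z).
// Positions outside [0, n-1] in any axis get `fill` and valid = FALSE.
// [[Rcpp::export]]
List trilinear_cpp(NumericVector vol, NumericMatrix pts, double fill) {
  IntegerVector dm = vol.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector ok(n);
  const double* v = REAL(vol);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = fill; ok[p] = false; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    #define V(i, j, k) v[(i) * sx + (j) * sy + (k) * sz]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
    ok[p] = true;
  }
  return List::create(_["values"] = out, _["valid"] = ok);
}

// Connected-component labels of a 3D logical array; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dm;
  const int* m = LOGICAL(mask);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != 1 || lab[s] != 0) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      int k = (int)(idx / ((R_xlen_t)nx * ny));
      int rem = (int)(idx % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            R_xlen_t nidx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (m[nidx] == 1 && lab[nidx] == 0) { lab[nidx] = cur; q.push(nidx); }
          }
    }
  }
  return lab;
}

// 8-connectivity labels of a 2D logical matrix.
// [[Rcpp::export]]
IntegerMatrix label2d_cpp(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int cur = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++cur;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> c = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = c.first + di, jj = c.second + dj;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = cur;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// Mean distance from each point to its k nearest neighbors (exact, O(n^2)).
// [[Rcpp::export]]
NumericVector knn_mean_dist_cpp(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = pts(i,0) - pts(j,0), dy = pts(i,1) - pts(j,1),
             dz = pts(i,2) - pts(j,2);
      d[j] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
    d[i] = R_PosInf;  // exclude self
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += d[j];
    out[i] = s / k;
  }
  return out;
}

// Index (1-based) of the nearest row of `nodes` for each row of `query`.
// [[Rcpp::export]]
IntegerVector nearest_node_cpp(NumericMatrix nodes, NumericMatrix query) {
  const int m = nodes.nrow(), n = query.nrow();
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    double best = R_PosInf; int bi = 1;
    double qx = query(p,0), qy = query(p,1), qz = query(p,2);
    for (int i = 0; i < m; ++i) {
      double dx = nodes(i,0) - qx, dy = nodes(i,1) - qy, dz = nodes(i,2) - qz;
      double dd = dx*dx + dy*dy + dz*dz;
      if (dd < best) { best = dd; bi = i + 1; }
    }
    out[p] = bi;
  }
  return out;
}
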