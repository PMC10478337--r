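// Voxel-mask utilities: 3D connected-component labelling (6-connectivity),
// binary box dilation, and exact nearest-neighbour point-set distances used
// by the Hausdorff metrics.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t p = q.front(); q.pop();
      const int z = p / ((size_t)nx * ny);
      const int rem = p - (size_t)z * nx * ny;
      const int y = rem / nx, x = rem % nx;
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const size_t pp = (size_t)xx + (size_t)nx * yy + (size_t)nx * ny * zz;
        if (mask[pp] && !lab[pp]) { lab[pp] = next; q.push(pp); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// box (Chebyshev-ball) dilation with radius r
// [[Rcpp::export(name = ".binary_dilate_3d")]]
LogicalVector binary_dilate_3d(LogicalVector mask, IntegerVector dims, int r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz, false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t p = (size_t)x + (size_t)nx * y + (size_t)nx * ny * z;
        if (!mask[p]) continue;
        for (int cz = std::max(0, z - r); cz <= std::min(nz - 1, z + r); ++cz)
          for (int cy = std::max(0, y - r); cy <= std::min(ny - 1, y + r); ++cy)
            for (int cx = std::max(0, x - r); cx <= std::min(nx - 1, x + r); ++cx)
              out[(size_t)cx + (size_t)nx * cy + (size_t)nx * ny * cz] = true;
      }
  out.attr("dim") = dims;
  return out;
}

// for every row of A (n x d) the Euclidean distance to the nearest row of B
// [[Rcpp::export(name = ".nn_dist_cpp")]]
NumericVector nn_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double v = A(i, k) - B(j, k);
        s += v * v;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
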