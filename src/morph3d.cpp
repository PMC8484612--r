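// 3D binary image primitives: connected-component labeling under
// 6/18/26-connectivity and iterative 6-neighbourhood erosion/dilation.
// Volumes are (ny, nx, nz) arrays in R's column-major order.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void neighbour_offsets(int conn, int ny, int nx, int nz,
                              std::vector<int>& dy, std::vector<int>& dx,
                              std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && nn > 1) continue;
        if (conn == 18 && nn > 2) continue;
        dy.push_back(a); dx.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> dy, dx, dz;
  neighbour_offsets(connectivity, ny, nx, nz, dy, dx, dz);
  const int ndir = (int)dy.size();
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  std::vector<R_xlen_t> queue;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v / ((R_xlen_t)ny * nx));
      int rem = (int)(v % ((R_xlen_t)ny * nx));
      int x = rem / ny, y = rem % ny;
      for (int d = 0; d < ndir; ++d) {
        int yy = y + dy[d], xx = x + dx[d], zz = z + dz[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[w] && !labels[w]) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}

static LogicalVector morph_pass(const LogicalVector& mask, bool erode) {
  IntegerVector dims = mask.attr("dim");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  LogicalVector out(n);
  out.attr("dim") = dims;
  const int dy[6] = {-1, 1, 0, 0, 0, 0};
  const int dx[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t v = 0; v < n; ++v) {
    int z = (int)(v / ((R_xlen_t)ny * nx));
    int rem = (int)(v % ((R_xlen_t)ny * nx));
    int x = rem / ny, y = rem % ny;
    bool val = mask[v];
    if (erode && val) {
      for (int d = 0; d < 6 && val; ++d) {
        int yy = y + dy[d], xx = x + dx[d], zz = z + dz[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;  // outside voxels do not erode the border
        R_xlen_t w = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (!mask[w]) val = false;
      }
    } else if (!erode && !val) {
      for (int d = 0; d < 6 && !val; ++d) {
        int yy = y + dy[d], xx = x + dx[d], zz = z + dz[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[w]) val = true;
      }
    }
    out[v] = val;
  }
  return out;
}

// [[Rcpp::export(name = ".binary_open3d")]]
LogicalVector binary_open3d(LogicalVector mask, int radius) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  if (radius < 0) stop("radius must be >= 0");
  LogicalVector cur = clone(mask);
  for (int r = 0; r < radius; ++r) cur = morph_pass(cur, true);
  for (int r = 0; r < radius; ++r) cur = morph_pass(cur, false);
  cur.attr("dim") = dims;
  return cur;
}
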