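#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for 6/18/26-connectivity on a 3D grid.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// Label connected components among the given voxels (1-based linear indices
// into a volume of dimensions `dims`). Returns one 1-based label per voxel.
// [[Rcpp::export]]
IntegerVector cc_label_voxels(IntegerVector idx, IntegerVector dims,
                              int connectivity = 18) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = idx.size();
  std::vector<int> pos(static_cast<size_t>(nx) * ny * nz, -1);
  for (R_xlen_t i = 0; i < n; ++i) pos[idx[i] - 1] = static_cast<int>(i);
  auto offs = neighbour_offsets(connectivity);
  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(static_cast<int>(i));
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int lin = idx[cur] - 1;
      int x = lin % nx, y = (lin / nx) % ny, z = lin / (nx * ny);
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int p = pos[xx + nx * (yy + static_cast<long long>(ny) * zz)];
        if (p >= 0 && labels[p] == 0) {
          labels[p] = next_label;
          stack.push_back(p);
        }
      }
    }
  }
  return labels;
}

// For each row of `tmat` (permutations x voxels), threshold at `thresh` and
// return the size of the largest connected suprathreshold cluster. `idx` maps
// the columns of `tmat` to 1-based linear voxel indices in a volume of
// dimensions `dims`.
// [[Rcpp::export]]
IntegerVector cc_max_cluster_sizes(NumericMatrix tmat, double thresh,
                                   IntegerVector idx, IntegerVector dims,
                                   int connectivity = 18) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nperm = tmat.nrow(), nvox = tmat.ncol();
  std::vector<int> pos(static_cast<size_t>(nx) * ny * nz, -1);
  std::vector<int> supra;
  std::vector<signed char> visited(nvox, 0);
  std::vector<int> stack;
  auto offs = neighbour_offsets(connectivity);
  IntegerVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    supra.clear();
    for (int v = 0; v < nvox; ++v) {
      if (tmat(p, v) > thresh) {
        supra.push_back(v);
        pos[idx[v] - 1] = v;
        visited[v] = 0;
      }
    }
    int best = 0;
    for (int s : supra) {
      if (visited[s]) continue;
      int size = 0;
      visited[s] = 1;
      stack.push_back(s);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int lin = idx[cur] - 1;
        int x = lin % nx, y = (lin / nx) % ny, z = lin / (nx * ny);
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int q = pos[xx + nx * (yy + static_cast<long long>(ny) * zz)];
          if (q >= 0 && !visited[q]) {
            visited[q] = 1;
            stack.push_back(q);
          }
        }
      }
      if (size > best) best = size;
    }
    for (int s : supra) pos[idx[s] - 1] = -1;  // reset for next permutation
    out[p] = best;
  }
  return out;
}
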