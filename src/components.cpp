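// 3D connected components and minimum-cluster-size filtering, applied
// volume by volume across a voxel-by-time matrix.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

static void build_offsets(int connectivity, std::vector<std::array<int, 3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// labels the connected components of `flag` (length nx*ny*nz, column-major);
// returns component labels (0 = background) and fills `sizes`
static void label_volume(const int* flag, int nx, int ny, int nz,
                         const std::vector<std::array<int, 3>>& off,
                         std::vector<int>& labels, std::vector<int>& sizes) {
  const int n = nx * ny * nz;
  labels.assign(n, 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!flag[i] || labels[i]) continue;
    ++next;
    int size = 0;
    stack.push_back(i);
    labels[i] = next;
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      ++size;
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (const auto& o : off) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int j = xx + nx * (yy + ny * zz);
        if (flag[j] && !labels[j]) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
    sizes.push_back(size);
  }
}

// [[Rcpp::export]]
IntegerVector label_components_3d(IntegerVector flag, IntegerVector dims,
                                  int connectivity = 6) {
  std::vector<std::array<int, 3>> off;
  build_offsets(connectivity, off);
  std::vector<int> labels, sizes;
  label_volume(INTEGER(flag), dims[0], dims[1], dims[2], off, labels, sizes);
  return IntegerVector(labels.begin(), labels.end());
}

// nonzero: V x T integer matrix (0/1); keeps, per timepoint, only voxels in
// connected components of size >= min_size
// [[Rcpp::export]]
LogicalMatrix cluster_size_filter(IntegerMatrix nonzero, IntegerVector dims,
                                  int min_size, int connectivity = 6) {
  const int V = nonzero.nrow(), T = nonzero.ncol();
  if (V != dims[0] * dims[1] * dims[2])
    stop("matrix rows do not match the grid");
  std::vector<std::array<int, 3>> off;
  build_offsets(connectivity, off);
  LogicalMatrix out(V, T);
  std::vector<int> labels, sizes;
  for (int t = 0; t < T; ++t) {
    const int* col = &nonzero(0, t);
    label_volume(col, dims[0], dims[1], dims[2], off, labels, sizes);
    for (int i = 0; i < V; ++i) {
      const int lab = labels[i];
      out(i, t) = lab > 0 && sizes[lab - 1] >= min_size;
    }
  }
  return out;
}
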