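#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Index reflection (half-sample symmetric): ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 1D convolution along one axis of a column-major nd array, reflective
// boundaries. Kernel length must be odd; axis is 0-based.
// [[Rcpp::export]]
NumericVector conv1d_axis_cpp(NumericVector arr, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nd = dims.size();
  if (axis < 0 || axis >= nd) stop("axis out of range");
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int half = klen / 2;
  const int len = dims[axis];

  R_xlen_t stride = 1;
  for (int d = 0; d < axis; ++d) stride *= dims[d];
  R_xlen_t n_outer = 1;
  for (int d = axis + 1; d < nd; ++d) n_outer *= dims[d];

  NumericVector out(arr.size());
  std::vector<double> line(len);

  for (R_xlen_t o = 0; o < n_outer; ++o) {
    for (R_xlen_t s = 0; s < stride; ++s) {
      const R_xlen_t base = o * stride * len + s;
      for (int j = 0; j < len; ++j) line[j] = arr[base + (R_xlen_t)j * stride];
      for (int j = 0; j < len; ++j) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          const int src = reflect_idx(j + k - half, len);
          acc += kernel[k] * line[src];
        }
        out[base + (R_xlen_t)j * stride] = acc;
      }
    }
  }
  return out;
}

// Neighbor offsets for a given connectivity.
// 2D: 4 (faces) or 8 (faces+corners); 3D: 6, 18 (faces+edges) or 26.
static std::vector<std::array<int, 3>> neighbor_offsets(int nd, int connectivity) {
  std::vector<std::array<int, 3>> offs;
  if (nd == 2) {
    if (connectivity != 4 && connectivity != 8)
      stop("2D connectivity must be 4 or 8");
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dy == 0 && dx == 0) continue;
        int manh = std::abs(dy) + std::abs(dx);
        if (connectivity == 4 && manh > 1) continue;
        offs.push_back({dy, dx, 0});
      }
  } else {
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
      stop("3D connectivity must be 6, 18 or 26");
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dy == 0 && dx == 0 && dz == 0) continue;
          int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
          if (connectivity == 6 && manh > 1) continue;
          if (connectivity == 18 && manh > 2) continue;
          offs.push_back({dy, dx, dz});
        }
  }
  return offs;
}

// Label connected components of a logical mask. Labels are assigned in
// column-major scan order of the first voxel of each component (1, 2, ...).
// dims is (y, x) or (y, x, z).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("mask must be 2D or 3D");
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  auto offs = neighbor_offsets(nd, connectivity);

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int y = cur % ny;
      const int x = (cur / ny) % nx;
      const int z = cur / ((R_xlen_t)ny * nx);
      for (const auto &o : offs) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Count connected components of (arr > threshold); cheaper than labeling
// when scanning many candidate thresholds.
// [[Rcpp::export]]
int count_components_cpp(NumericVector arr, IntegerVector dims,
                         double threshold, int connectivity) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  auto offs = neighbor_offsets(nd, connectivity);

  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> stack;
  int count = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (visited[i] || !(arr[i] > threshold)) continue;
    ++count;
    visited[i] = 1;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int y = cur % ny;
      const int x = (cur / ny) % nx;
      const int z = cur / ((R_xlen_t)ny * nx);
      for (const auto &o : offs) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
        if (!visited[j] && arr[j] > threshold) {
          visited[j] = 1;
          stack.push_back(j);
        }
      }
    }
  }
  return count;
}

// Moving-sphere (disc in 2D) median filter with reflective boundaries.
// [[Rcpp::export]]
NumericVector sphere_median_cpp(NumericVector arr, IntegerVector dims,
                                int radius) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("array must be 2D or 3D");
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (radius < 1) stop("radius must be >= 1");

  // spherical footprint offsets
  std::vector<std::array<int, 3>> offs;
  const int zr = (nd == 3) ? radius : 0;
  for (int dz = -zr; dz <= zr; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dy * dy + dx * dx + dz * dz <= radius * radius)
          offs.push_back({dy, dx, dz});
  const size_t m = offs.size();

  NumericVector out(n);
  std::vector<double> vals(m);

  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        for (size_t k = 0; k < m; ++k) {
          const int yy = reflect_idx(y + offs[k][0], ny);
          const int xx = reflect_idx(x + offs[k][1], nx);
          const int zz = (nd == 3) ? reflect_idx(z + offs[k][2], nz) : 0;
          vals[k] = arr[(R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy];
        }
        const size_t mid = m / 2;
        std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
        double med = vals[mid];
        if (m % 2 == 0) {
          const double lo = *std::max_element(vals.begin(), vals.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[(R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y] = med;
      }
    }
  }
  return out;
}

// Moving-sphere mean of `arr` over voxels NOT flagged in `mask` (the
// detected spot territory); reflective boundaries. Voxels whose whole
// sphere is masked fall back to the global unmasked mean.
// [[Rcpp::export]]
NumericVector sphere_mean_masked_cpp(NumericVector arr, LogicalVector mask,
                                     IntegerVector dims, int radius) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("array must be 2D or 3D");
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (radius < 1) stop("radius must be >= 1");

  std::vector<std::array<int, 3>> offs;
  const int zr = (nd == 3) ? radius : 0;
  for (int dz = -zr; dz <= zr; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dy * dy + dx * dx + dz * dz <= radius * radius)
          offs.push_back({dy, dx, dz});

  double gsum = 0.0; R_xlen_t gcnt = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (!mask[i]) { gsum += arr[i]; ++gcnt; }
  const double gmean = gcnt > 0 ? gsum / gcnt : 0.0;

  NumericVector out(n);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double s = 0.0; int c = 0;
        for (size_t k = 0; k < offs.size(); ++k) {
          const int yy = reflect_idx(y + offs[k][0], ny);
          const int xx = reflect_idx(x + offs[k][1], nx);
          const int zz = (nd == 3) ? reflect_idx(z + offs[k][2], nz) : 0;
          const R_xlen_t j = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
          if (!mask[j]) { s += arr[j]; ++c; }
        }
        out[(R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y] =
          c > 0 ? s / c : gmean;
      }
    }
  }
  return out;
}

// Grow labeled components outward by `pad` Chebyshev steps; each newly
// claimed voxel takes the minimum adjacent label (deterministic tie-break).
// [[Rcpp::export]]
IntegerVector grow_labels_cpp(IntegerVector labels, IntegerVector dims,
                              int pad) {
  const int nd = dims.size();
  const int ny = dims[0], nx = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  auto offs = neighbor_offsets(nd, nd == 2 ? 8 : 26);

  IntegerVector cur = clone(labels);
  for (int round = 0; round < pad; ++round) {
    IntegerVector nxt = clone(cur);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (cur[i] != 0) continue;
      const int y = i % ny;
      const int x = (i / ny) % nx;
      const int z = i / ((R_xlen_t)ny * nx);
      int best = 0;
      for (const auto &o : offs) {
        const int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        const int lab = cur[(R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy];
        if (lab > 0 && (best == 0 || lab < best)) best = lab;
      }
      if (best > 0) nxt[i] = best;
    }
    cur = nxt;
  }
  return cur;
}
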