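#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Internal voxel layout everywhere: dim = (H, W, Z), column-major, so the
// linear index of (y, x, z) [0-based here] is y + H*x + H*W*z.  Scan order
// used for deterministic label assignment is this linear order.

namespace {

struct Offsets {
  std::vector<int> dy, dx, dz;
};

// connectivity: 6, 18 or 26 (3D).  2D callers pass a single-slice array
// with 6 -> 4-neighbourhood in-plane, 26 -> 8-neighbourhood in-plane.
Offsets make_offsets(int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int m = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (m == 0) continue;
        int maxm = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
        if (m > maxm) continue;
        o.dy.push_back(dy); o.dx.push_back(dx); o.dz.push_back(dz);
      }
  return o;
}

inline void check_dim3(const IntegerVector& v, int& H, int& W, int& Z) {
  SEXP d = v.attr("dim");
  if (Rf_isNull(d)) stop("array must have a dim attribute");
  IntegerVector dim(d);
  if (dim.size() != 3) stop("array must be 3-dimensional (H, W, Z)");
  H = dim[0]; W = dim[1]; Z = dim[2];
  if (H < 1 || W < 1 || Z < 1) stop("all dimensions must be >= 1");
}

} // namespace

// [[Rcpp::export(name = ".cpp_median_filter")]]
IntegerVector cpp_median_filter(IntegerVector vox, int radius) {
  int H, W, Z;
  check_dim3(vox, H, W, Z);
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(vox);
  IntegerVector out(vox.size());
  out.attr("dim") = vox.attr("dim");
  int win = 2 * radius + 1;
  std::vector<int> buf;
  buf.reserve(win * win);
  for (int z = 0; z < Z; ++z) {
    const int* src = vox.begin() + (R_xlen_t)z * H * W;
    int* dst = out.begin() + (R_xlen_t)z * H * W;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        buf.clear();
        // border policy: edge replication (clamp indices into the slice)
        for (int dx = -radius; dx <= radius; ++dx) {
          int xx = std::min(std::max(x + dx, 0), W - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            int yy = std::min(std::max(y + dy, 0), H - 1);
            buf.push_back(src[yy + H * xx]);
          }
        }
        size_t mid = buf.size() / 2; // odd count: exact middle
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        dst[y + H * x] = buf[mid];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_region_grow")]]
LogicalVector cpp_region_grow(IntegerVector vox, int seed_y, int seed_x,
                              int seed_z, int theta_min, int theta_max,
                              int connectivity) {
  int H, W, Z;
  check_dim3(vox, H, W, Z);
  if (seed_y < 0 || seed_y >= H || seed_x < 0 || seed_x >= W ||
      seed_z < 0 || seed_z >= Z)
    stop("seed out of bounds");
  Offsets off = make_offsets(connectivity);
  LogicalVector mask(vox.size(), false);
  mask.attr("dim") = vox.attr("dim");
  R_xlen_t seed = seed_y + (R_xlen_t)H * seed_x + (R_xlen_t)H * W * seed_z;
  int sval = vox[seed];
  if (sval < theta_min || sval > theta_max)
    stop("seed intensity outside threshold range");
  std::queue<R_xlen_t> q;
  mask[seed] = true;
  q.push(seed);
  R_xlen_t HW = (R_xlen_t)H * W;
  while (!q.empty()) {
    R_xlen_t i = q.front(); q.pop();
    int z = (int)(i / HW);
    int rem = (int)(i % HW);
    int x = rem / H, y = rem % H;
    for (size_t k = 0; k < off.dy.size(); ++k) {
      int yy = y + off.dy[k], xx = x + off.dx[k], zz = z + off.dz[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W || zz < 0 || zz >= Z)
        continue;
      R_xlen_t j = yy + (R_xlen_t)H * xx + HW * zz;
      if (mask[j]) continue;
      int v = vox[j];
      if (v >= theta_min && v <= theta_max) {
        mask[j] = true;
        q.push(j);
      }
    }
  }
  return mask;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  int H, W, Z;
  check_dim3(mask, H, W, Z);
  Offsets off = make_offsets(connectivity);
  IntegerVector labels(mask.size(), 0);
  labels.attr("dim") = mask.attr("dim");
  R_xlen_t HW = (R_xlen_t)H * W, N = mask.size();
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int z = (int)(i / HW);
      int rem = (int)(i % HW);
      int x = rem / H, y = rem % H;
      for (size_t k = 0; k < off.dy.size(); ++k) {
        int yy = y + off.dy[k], xx = x + off.dx[k], zz = z + off.dz[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W || zz < 0 || zz >= Z)
          continue;
        R_xlen_t j = yy + (R_xlen_t)H * xx + HW * zz;
        if (mask[j] != 0 && labels[j] == 0) {
          labels[j] = next;
          q.push(j);
        }
      }
    }
  }
  return labels;
}
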