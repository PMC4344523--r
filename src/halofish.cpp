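#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// All arrays are R column-major with dim = (d1, d2, d3); linear index
// i1 + d1 * (i2 + d2 * i3).

static inline int reflect_idx(int i, int n) {
  // mirror boundary without repeating the edge sample (whole-sample symmetry)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// convolve all lines along `axis` through a reflect-padded line buffer, so
// the inner tap loop is a plain dot product
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int d1, int d2, int d3, int axis,
                      const NumericVector &k) {
  const int kh = (k.size() - 1) / 2;
  const int dims[3] = {d1, d2, d3};
  const size_t strides[3] = {1, (size_t)d1, (size_t)d1 * d2};
  const int n = dims[axis];
  const size_t stride = strides[axis];
  const double *kp = &k[0];
  const int klen = k.size();
  std::vector<double> buf(n + 2 * kh);

  // iterate over all lines: the two non-axis dimensions
  int oa = (axis == 0) ? 1 : 0;
  int ob = (axis == 2) ? 1 : 2;
  for (int ib = 0; ib < dims[ob]; ++ib) {
    for (int ia = 0; ia < dims[oa]; ++ia) {
      size_t base = (size_t)ia * strides[oa] + (size_t)ib * strides[ob];
      for (int i = 0; i < n; ++i) buf[kh + i] = in[base + (size_t)i * stride];
      for (int t = 1; t <= kh; ++t) {
        buf[kh - t] = buf[kh + reflect_idx(-t, n)];
        buf[kh + n - 1 + t] = buf[kh + reflect_idx(n - 1 + t, n)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *bp = &buf[i];
        for (int t = 0; t < klen; ++t) acc += kp[t] * bp[t];
        out[base + (size_t)i * stride] = acc;
      }
    }
  }
}

// Separable 3D convolution with symmetric (reflective) boundary handling.
// Kernels k1, k2, k3 act along dimensions 1, 2, 3; any may have length 1.
// [[Rcpp::export]]
NumericVector conv_sep3_cpp(NumericVector arr, IntegerVector dim,
                            NumericVector k1, NumericVector k2,
                            NumericVector k3) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)arr.size() != n) stop("array size does not match dim");
  if (k1.size() % 2 == 0 || k2.size() % 2 == 0 || k3.size() % 2 == 0)
    stop("kernels must have odd length");
  if (k1.size() > 2 * d1 - 1 || k2.size() > 2 * d2 - 1 || k3.size() > 2 * d3 - 1)
    stop("kernel larger than image extent");
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  const std::vector<double> *src = &a;
  std::vector<double> *dst = &b;
  if (k1.size() > 1) { conv_axis(*src, *dst, d1, d2, d3, 0, k1); std::swap(a, b); }
  if (k2.size() > 1) { conv_axis(a, b, d1, d2, d3, 1, k2); std::swap(a, b); }
  if (k3.size() > 1) { conv_axis(a, b, d1, d2, d3, 2, k3); std::swap(a, b); }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 (26-neighborhood) maximum filter, separable per axis.
// [[Rcpp::export]]
NumericVector max_filter3_cpp(NumericVector arr, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)arr.size() != n) stop("array size does not match dim");
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  const int dims[3] = {d1, d2, d3};
  const size_t strides[3] = {1, (size_t)d1, (size_t)d1 * d2};
  for (int axis = 0; axis < 3; ++axis) {
    const int m = dims[axis];
    const size_t stride = strides[axis];
    if (m < 2) continue;
    int oa = (axis == 0) ? 1 : 0;
    int ob = (axis == 2) ? 1 : 2;
    for (int ib = 0; ib < dims[ob]; ++ib) {
      for (int ia = 0; ia < dims[oa]; ++ia) {
        size_t base = (size_t)ia * strides[oa] + (size_t)ib * strides[ob];
        for (int i = 0; i < m; ++i) {
          double v = a[base + (size_t)i * stride];
          if (i > 0) v = std::max(v, a[base + (size_t)(i - 1) * stride]);
          if (i < m - 1) v = std::max(v, a[base + (size_t)(i + 1) * stride]);
          b[base + (size_t)i * stride] = v;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling of a logical mask. connectivity: 6 or 26.
// Labels are assigned in raster-scan order of the first voxel encountered,
// so the result is deterministic.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)mask.size() != n) stop("mask size does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector labels(n, 0);
  std::vector<size_t> stack;
  int next_label = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int i1 = v % d1;
      int i2 = (v / d1) % d2;
      int i3 = v / ((size_t)d1 * d2);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
            if (connectivity == 6 && manh != 1) continue;
            int j1 = i1 + dz, j2 = i2 + dy, j3 = i3 + dx;
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
              continue;
            size_t w = j1 + (size_t)d1 * (j2 + (size_t)d2 * j3);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

struct WsEntry {
  double intensity;
  uint64_t order;
  size_t idx;
};

struct WsCompare {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.intensity != b.intensity) return a.intensity < b.intensity;
    return a.order > b.order;  // FIFO among equal intensities -> deterministic
  }
};

// Marker-based watershed by descending-intensity flooding, restricted to
// `mask`. `markers` holds positive seed labels (zero elsewhere). Voxels in
// the mask reachable from a seed adopt the label of the highest-intensity
// front that reaches them first.
// [[Rcpp::export]]
IntegerVector watershed_markers_cpp(NumericVector intensity,
                                    IntegerVector markers, LogicalVector mask,
                                    IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t n = (size_t)d1 * d2 * d3;
  if ((size_t)intensity.size() != n || (size_t)markers.size() != n ||
      (size_t)mask.size() != n)
    stop("input sizes do not match dim");
  IntegerVector labels(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  uint64_t counter = 0;
  for (size_t v = 0; v < n; ++v) {
    if (markers[v] > 0 && mask[v]) {
      labels[v] = markers[v];
      pq.push(WsEntry{intensity[v], counter++, v});
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    size_t v = e.idx;
    int i1 = v % d1;
    int i2 = (v / d1) % d2;
    int i3 = v / ((size_t)d1 * d2);
    int lab = labels[v];
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;
          int j1 = i1 + dz, j2 = i2 + dy, j3 = i3 + dx;
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          size_t w = j1 + (size_t)d1 * (j2 + (size_t)d2 * j3);
          if (mask[w] && labels[w] == 0) {
            labels[w] = lab;
            pq.push(WsEntry{intensity[w], counter++, w});
          }
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
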