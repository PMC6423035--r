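#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D connected-component labelling of a binary volume stored column-major
// (R array semantics: linear index = i + n0*j + n0*n1*k, 0-based).
// Seeds are visited in ascending linear-index ("raster") order, so labels are
// numbered by each component's first raster voxel; ties between equal-sized
// components are therefore resolvable deterministically by label order.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cc_label3d(const LogicalVector& mask, const IntegerVector& dims,
                         int connectivity) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> off_i, off_j, off_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (man == 0) continue;
        if (connectivity == 6 && man != 1) continue;
        off_i.push_back(di); off_j.push_back(dj); off_k.push_back(dk);
      }
  const int noff = (int)off_i.size();

  IntegerVector labels(n, 0);
  int current = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    q.push(seed);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      int k = (int)(idx / s2);
      int rem = (int)(idx - (R_xlen_t)k * s2);
      int j = rem / n0;
      int i = rem - j * n0;
      for (int t = 0; t < noff; ++t) {
        int ii = i + off_i[t], jj = j + off_j[t], kk = k + off_k[t];
        if (ii < 0 || ii >= n0 || jj < 0 || jj >= n1 || kk < 0 || kk >= n2)
          continue;
        R_xlen_t nb = ii + s1 * jj + s2 * kk;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = current;
          q.push(nb);
        }
      }
    }
  }
  labels.attr("label_count") = current;
  return labels;
}

static inline int reflect_index(int p, int n) {
  // half-sample symmetric reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -p - 1;
    if (p >= n) p = 2 * n - 1 - p;
  }
  return p;
}

// Convolve a 3D volume (column-major) along one axis (0,1,2) with an odd-length
// kernel, reflecting at the boundaries. Used to build separable Gaussian
// smoothing; reflection preserves constants for any normalized kernel.
// [[Rcpp::export]]
NumericVector conv_axis3d(const NumericVector& x, const IntegerVector& dims,
                          const NumericVector& kernel, int axis) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (x.size() != n) stop("volume length does not match dims");
  if (kernel.size() % 2 == 0) stop("kernel length must be odd");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int r = ((int)kernel.size() - 1) / 2;

  int nax, nA, nB;
  R_xlen_t stride, strideA, strideB;
  const R_xlen_t s1 = n0, s2 = (R_xlen_t)n0 * n1;
  if (axis == 0)      { nax = n0; stride = 1;  nA = n1; strideA = s1; nB = n2; strideB = s2; }
  else if (axis == 1) { nax = n1; stride = s1; nA = n0; strideA = 1;  nB = n2; strideB = s2; }
  else                { nax = n2; stride = s2; nA = n0; strideA = 1;  nB = n1; strideB = s1; }

  NumericVector out(n);
  std::vector<double> fib(nax);
  for (int b = 0; b < nB; ++b) {
    for (int a = 0; a < nA; ++a) {
      const R_xlen_t base = (R_xlen_t)a * strideA + (R_xlen_t)b * strideB;
      for (int p = 0; p < nax; ++p) fib[p] = x[base + (R_xlen_t)p * stride];
      for (int p = 0; p < nax; ++p) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t)
          acc += kernel[t + r] * fib[reflect_index(p + t, nax)];
        out[base + (R_xlen_t)p * stride] = acc;
      }
    }
  }
  return out;
}
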