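// Low-level 3D raster operations: squared Euclidean distance transform,
// connected-component labeling, separable Gaussian smoothing, local
// thickness (largest inscribed sphere), and polygon rasterization.
// Arrays are R column-major; dim = (n1, n2, n3) with axis 1 axial.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared distance transform, lower envelope of parabolas
// (Felzenszwalb & Huttenlocher 2012)
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units, center-to-center) from every
// voxel to the nearest TRUE voxel. Voxels outside the array are ignored.
// If the mask is empty, all distances are DT_INF-scale.
// [[Rcpp::export]]
NumericVector cpp_sqdist_to_mask(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector D(N);
  for (R_xlen_t i = 0; i < N; i++) D[i] = mask[i] ? 0.0 : DT_INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = D[base + i];
      dt1d(f, d, n1, v, z);
      for (int i = 0; i < n1; i++) D[base + i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = D[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2, v, z);
      for (int j = 0; j < n2; j++) D[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; k++) f[k] = D[base + s3 * k];
      dt1d(f, d, n3, v, z);
      for (int k = 0; k < n3; k++) D[base + s3 * k] = d[k];
    }
  return D;
}

// Connected-component labeling (6 or 26 connectivity), BFS seeded in
// raster order so label numbering is deterministic: the component whose
// first voxel comes earliest in column-major order gets label 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);

  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  int nn = (int)d1.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t idx = 0; idx < N; idx++) {
    if (!mask[idx] || lab[idx] != 0) continue;
    next++;
    lab[idx] = next;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < nn; t++) {
        int ii = i + d1[t], jj = j + d2[t], kk = k + d3[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          q.push(nb);
        }
      }
    }
  }
  return lab;
}

static inline int reflect_index(int i, int n) {
  // half-sample symmetric boundary: -1 -> 0, -2 -> 1, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable Gaussian smoothing; kernel truncated at `radius` voxels and
// renormalized to unit sum after truncation. Reflecting boundaries, so a
// constant field is preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_gaussian3(NumericVector vol, IntegerVector dim,
                            double sigma, int radius) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  if (sigma <= 0.0 || radius < 1) return clone(vol);

  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int k = -radius; k <= radius; k++) {
    w[k + radius] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += w[k + radius];
  }
  for (size_t k = 0; k < w.size(); k++) w[k] /= s;

  NumericVector A = clone(vol);
  NumericVector B(N);
  R_xlen_t s3 = (R_xlen_t)n1 * n2;

  // axis 1
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * j + s3 * k;
      for (int i = 0; i < n1; i++) {
        double acc = 0.0;
        for (int t = -radius; t <= radius; t++)
          acc += w[t + radius] * A[base + reflect_index(i + t, n1)];
        B[base + i] = acc;
      }
    }
  std::swap(A, B);
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + s3 * k;
      for (int j = 0; j < n2; j++) {
        double acc = 0.0;
        for (int t = -radius; t <= radius; t++)
          acc += w[t + radius] * A[base + (R_xlen_t)n1 * reflect_index(j + t, n2)];
        B[base + (R_xlen_t)n1 * j] = acc;
      }
    }
  std::swap(A, B);
  // axis 3
  if (n3 > 1) {
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t base = i + (R_xlen_t)n1 * j;
        for (int k = 0; k < n3; k++) {
          double acc = 0.0;
          for (int t = -radius; t <= radius; t++)
            acc += w[t + radius] * A[base + s3 * reflect_index(k + t, n3)];
          B[base + s3 * k] = acc;
        }
      }
    std::swap(A, B);
  }
  return A;
}

// Model-independent local thickness (Hildebrand & Rüegsegger): thickness
// at a voxel is the diameter of the largest sphere that fits in the
// structure and contains the voxel. Sphere radii come from the EDT to the
// background, offset by half a voxel (center-to-boundary distance).
// Returns thickness in voxel units (0 outside the mask).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = (dim.size() > 2) ? dim[2] : 1;
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;

  LogicalVector inv(N);
  for (R_xlen_t i = 0; i < N; i++) inv[i] = !mask[i];
  NumericVector D = cpp_sqdist_to_mask(inv, dim);

  std::vector<std::pair<double, R_xlen_t> > centers;
  centers.reserve(1024);
  for (R_xlen_t i = 0; i < N; i++) {
    if (!mask[i]) continue;
    if (D[i] >= DT_INF) stop("mask has no background voxels");
    double r = std::sqrt(D[i]) - 0.5;
    if (r < 0.5) r = 0.5;  // every voxel holds at least a one-voxel sphere
    centers.push_back(std::make_pair(r, i));
  }
  std::sort(centers.begin(), centers.end(),
            std::greater<std::pair<double, R_xlen_t> >());

  NumericVector th(N, 0.0);
  for (size_t c = 0; c < centers.size(); c++) {
    double r = centers[c].first;
    R_xlen_t idx = centers[c].second;
    double dia = 2.0 * r;
    if (th[idx] >= dia) continue;  // sphere cannot improve its own center
    int i = (int)(idx % n1);
    int j = (int)((idx / n1) % n2);
    int k = (int)(idx / ((R_xlen_t)n1 * n2));
    int ir = (int)std::floor(r + 1e-9);
    double r2 = r * r + 1e-9;
    for (int a = std::max(0, i - ir); a <= std::min(n1 - 1, i + ir); a++)
      for (int b = std::max(0, j - ir); b <= std::min(n2 - 1, j + ir); b++)
        for (int d3 = std::max(0, k - ir); d3 <= std::min(n3 - 1, k + ir); d3++) {
          double dd = (double)(a - i) * (a - i) + (double)(b - j) * (b - j) +
                      (double)(d3 - k) * (d3 - k);
          if (dd > r2) continue;
          R_xlen_t nb = a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * d3);
          if (mask[nb] && th[nb] < dia) th[nb] = dia;
        }
  }
  return th;
}

// Fill a polygon on a pixel grid: a pixel belongs to the interior when its
// center lies inside (even-odd rule) or exactly on the polygon boundary.
// poly: m x 2 matrix of (row, col) vertices in 0-based pixel coordinates.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(NumericMatrix poly, int nrow_out,
                                    int ncol_out) {
  int m = poly.nrow();
  LogicalMatrix out(nrow_out, ncol_out);
  const double eps = 1e-9;
  for (int a = 0; a < nrow_out; a++) {
    for (int b = 0; b < ncol_out; b++) {
      double y = a, x = b;
      bool on = false, in = false;
      for (int e = 0; e < m; e++) {
        double y1 = poly(e, 0), x1 = poly(e, 1);
        int e2 = (e + 1) % m;
        double y2 = poly(e2, 0), x2 = poly(e2, 1);
        double cross = (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1);
        double scale = std::fabs(x2 - x1) + std::fabs(y2 - y1) + 1.0;
        if (std::fabs(cross) < eps * scale &&
            x >= std::min(x1, x2) - eps && x <= std::max(x1, x2) + eps &&
            y >= std::min(y1, y2) - eps && y <= std::max(y1, y2) + eps) {
          on = true;
          break;
        }
        if ((y1 > y) != (y2 > y)) {
          double xin = x1 + (y - y1) / (y2 - y1) * (x2 - x1);
          if (x < xin) in = !in;
        }
      }
      out(a, b) = on || in;
    }
  }
  return out;
}
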