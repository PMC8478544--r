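// Iso-surface triangulation (marching tetrahedra on the Kuhn cube
// decomposition) and 2D iso-contour extraction. The Kuhn split is
// translation-consistent (shared cube faces receive the same diagonal),
// so the triangulation of a padded field is closed and 2-manifold.
// Edge-crossing vertices are interpolated with canonically ordered
// endpoints, so shared vertices agree bit-for-bit across tetrahedra.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

struct Corner {
  int o1, o2, o3;  // offsets within the unit cube
};

// Interpolate the level crossing on edge (p, q); endpoints ordered by
// global linear index so both incident tetrahedra compute the same point.
static inline void edge_point(const double* cp, const double* cq,
                              double vp, double vq,
                              long gp, long gq, double level, double* out) {
  if (gp > gq) {
    std::swap(cp, cq);
    std::swap(vp, vq);
  }
  double t = (level - vp) / (vq - vp);
  for (int d = 0; d < 3; d++) out[d] = cp[d] + t * (cq[d] - cp[d]);
}

// [[Rcpp::export]]
NumericMatrix cpp_iso_triangles(NumericVector vol, IntegerVector dim,
                                double level) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<double> tris;  // 9 doubles per triangle
  tris.reserve(4096);

  // per-permutation corner chains: (0,0,0) -> +e_p0 -> +e_p1 -> +e_p2
  Corner chains[6][4];
  for (int p = 0; p < 6; p++) {
    int o[3] = {0, 0, 0};
    chains[p][0].o1 = 0; chains[p][0].o2 = 0; chains[p][0].o3 = 0;
    for (int s = 0; s < 3; s++) {
      o[PERMS[p][s]] += 1;
      chains[p][s + 1].o1 = o[0];
      chains[p][s + 1].o2 = o[1];
      chains[p][s + 1].o3 = o[2];
    }
  }

  double C[4][3], P[3], Q[3], R2[3], S[3];
  double V[4];
  long G[4];

  for (int k = 0; k < n3 - 1; k++)
    for (int j = 0; j < n2 - 1; j++)
      for (int i = 0; i < n1 - 1; i++) {
        // quick reject: all 8 corners on one side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int a = i + (c & 1), b = j + ((c >> 1) & 1), d = k + ((c >> 2) & 1);
          double v = vol[a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * d)];
          if (v >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int p = 0; p < 6; p++) {
          int nin = 0;
          int in_idx[4], out_idx[4];
          int nout = 0;
          for (int c = 0; c < 4; c++) {
            int a = i + chains[p][c].o1;
            int b = j + chains[p][c].o2;
            int d = k + chains[p][c].o3;
            C[c][0] = a; C[c][1] = b; C[c][2] = d;
            G[c] = a + (long)n1 * (b + (long)n2 * d);
            V[c] = vol[(R_xlen_t)G[c]];
            if (V[c] >= level) in_idx[nin++] = c; else out_idx[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_idx[0] : out_idx[0];
            double* pts[3] = {P, Q, R2};
            int t = 0;
            for (int c = 0; c < 4; c++) {
              if (c == apex) continue;
              edge_point(C[apex], C[c], V[apex], V[c], G[apex], G[c], level,
                         pts[t++]);
            }
            for (int d = 0; d < 3; d++) tris.push_back(P[d]);
            for (int d = 0; d < 3; d++) tris.push_back(Q[d]);
            for (int d = 0; d < 3; d++) tris.push_back(R2[d]);
          } else {
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            edge_point(C[a], C[c], V[a], V[c], G[a], G[c], level, P);
            edge_point(C[a], C[d], V[a], V[d], G[a], G[d], level, Q);
            edge_point(C[b], C[d], V[b], V[d], G[b], G[d], level, R2);
            edge_point(C[b], C[c], V[b], V[c], G[b], G[c], level, S);
            for (int t = 0; t < 3; t++) tris.push_back(P[t]);
            for (int t = 0; t < 3; t++) tris.push_back(Q[t]);
            for (int t = 0; t < 3; t++) tris.push_back(R2[t]);
            for (int t = 0; t < 3; t++) tris.push_back(P[t]);
            for (int t = 0; t < 3; t++) tris.push_back(R2[t]);
            for (int t = 0; t < 3; t++) tris.push_back(S[t]);
          }
        }
      }

  int ntri = (int)(tris.size() / 9);
  NumericMatrix out(ntri, 9);
  for (int r = 0; r < ntri; r++)
    for (int c = 0; c < 9; c++) out(r, c) = tris[(size_t)r * 9 + c];
  return out;
}

// 2D iso-contour segments via the same simplex scheme: each pixel cell is
// split into two triangles along the (0,0)-(1,1) diagonal. Returns one row
// (y1, x1, y2, x2) per segment, coordinates in 0-based pixel units.
// [[Rcpp::export]]
NumericMatrix cpp_iso_segments2d(NumericMatrix img, double level) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> segs;
  segs.reserve(1024);

  const int TRIS[2][3][2] = {{{0, 0}, {1, 0}, {1, 1}},
                             {{0, 0}, {1, 1}, {0, 1}}};
  double C[3][2], V[3], P[2], Q[2];
  long G[3];

  for (int j = 0; j < nc - 1; j++)
    for (int i = 0; i < nr - 1; i++)
      for (int t = 0; t < 2; t++) {
        int nin = 0, in_idx[3], out_idx[3], nout = 0;
        for (int c = 0; c < 3; c++) {
          int a = i + TRIS[t][c][0], b = j + TRIS[t][c][1];
          C[c][0] = a; C[c][1] = b;
          G[c] = a + (long)nr * b;
          V[c] = img(a, b);
          if (V[c] >= level) in_idx[nin++] = c; else out_idx[nout++] = c;
        }
        if (nin == 0 || nin == 3) continue;
        int apex = (nin == 1) ? in_idx[0] : out_idx[0];
        int o1 = -1, o2 = -1;
        for (int c = 0; c < 3; c++) {
          if (c == apex) continue;
          if (o1 < 0) o1 = c; else o2 = c;
        }
        const double* cp;
        const double* cq;
        double vp, vq;
        // edge apex-o1
        cp = C[apex]; cq = C[o1]; vp = V[apex]; vq = V[o1];
        if (G[apex] > G[o1]) { std::swap(cp, cq); std::swap(vp, vq); }
        double s = (level - vp) / (vq - vp);
        P[0] = cp[0] + s * (cq[0] - cp[0]);
        P[1] = cp[1] + s * (cq[1] - cp[1]);
        // edge apex-o2
        cp = C[apex]; cq = C[o2]; vp = V[apex]; vq = V[o2];
        if (G[apex] > G[o2]) { std::swap(cp, cq); std::swap(vp, vq); }
        s = (level - vp) / (vq - vp);
        Q[0] = cp[0] + s * (cq[0] - cp[0]);
        Q[1] = cp[1] + s * (cq[1] - cp[1]);
        segs.push_back(P[0]); segs.push_back(P[1]);
        segs.push_back(Q[0]); segs.push_back(Q[1]);
      }

  int nseg = (int)(segs.size() / 4);
  NumericMatrix out(nseg, 4);
  for (int r = 0; r < nseg; r++)
    for (int c = 0; c < 4; c++) out(r, c) = segs[(size_t)r * 4 + c];
  return out;
}
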