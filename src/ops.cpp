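#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D arrays are passed as flat vectors in R's column-major layout:
// index = i + nx*(j + ny*k).

// Separable Gaussian filter with per-axis sigma (voxels). Kernel
// truncated at 3 sigma and renormalized at the borders so constants are
// preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  NumericVector src = clone(arr);
  NumericVector dst(n);
  const int ndim[3] = {nx, ny, nz};
  // strides for each axis
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    const double sg = sigma[axis];
    if (sg <= 0) continue;
    int rad = (int)std::ceil(3.0 * sg);
    if (rad < 1) rad = 1;
    std::vector<double> w(2 * rad + 1);
    for (int d = -rad; d <= rad; ++d)
      w[d + rad] = std::exp(-0.5 * d * d / (sg * sg));
    const int len = ndim[axis];
    const R_xlen_t st = stride[axis];
    // iterate over all lines along `axis`
    const int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
    for (int b = 0; b < ndim[ob]; ++b) {
      for (int a = 0; a < ndim[oa]; ++a) {
        const R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
        for (int i = 0; i < len; ++i) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, i - rad), hi = std::min(len - 1, i + rad);
          for (int j = lo; j <= hi; ++j) {
            double wj = w[j - i + rad];
            acc += wj * src[base + (R_xlen_t)j * st];
            wsum += wj;
          }
          dst[base + (R_xlen_t)i * st] = acc / wsum;
        }
      }
    }
    std::swap(src, dst);
  }
  return src;
}

// Binary dilation by an explicit offset list (m x 3 integer matrix).
// Voxels outside the grid are treated as background.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const int m = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        for (int o = 0; o < m; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
              kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          out[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] = true;
        }
      }
  return out;
}

// Binary erosion by an explicit offset list; outside the grid counts as
// background, so foreground touching the border erodes.
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const int m = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        bool keep = true;
        for (int o = 0; o < m; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
              kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
            keep = false; break;
          }
          if (!mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
            keep = false; break;
          }
        }
        out[idx] = keep;
      }
  return out;
}

// 6-connected component labelling of a binary grid. Returns an integer
// grid with 0 for background and 1..n_components for foreground.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t dstep[6] = {1, -1, (R_xlen_t)nx, -(R_xlen_t)nx,
                             (R_xlen_t)nx * ny, -(R_xlen_t)nx * ny};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i, jj = j, kk = k;
        if (d == 0) ++ii; else if (d == 1) --ii;
        else if (d == 2) ++jj; else if (d == 3) --jj;
        else if (d == 4) ++kk; else --kk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t w = v + dstep[d];
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ---- marching tetrahedra -------------------------------------------------
// Each grid cell is split into 6 tetrahedra sharing the main diagonal
// (corner 0 to corner 6); face diagonals agree between neighbouring cells,
// so the surface is conformal (watertight on closed level sets). Vertices
// are welded through a grid-edge hash, giving shared connectivity.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static inline int edge_point(MTState &st, uint64_t g1, uint64_t g2,
                             double x1, double y1, double z1, double f1v,
                             double x2, double y2, double z2, double f2v,
                             double level) {
  if (g1 > g2) {
    std::swap(g1, g2);
    std::swap(x1, x2); std::swap(y1, y2); std::swap(z1, z2);
    std::swap(f1v, f2v);
  }
  uint64_t key = (g1 << 32) | g2;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (level - f1v) / (f2v - f1v);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  int id = (int)st.vx.size();
  st.vx.push_back(x1 + t * (x2 - x1));
  st.vy.push_back(y1 + t * (y2 - y1));
  st.vz.push_back(z1 + t * (z2 - z1));
  st.edge_vertex.emplace(key, id);
  return id;
}

static inline void emit_tri(MTState &st, int a, int b, int c,
                            double ox, double oy, double oz) {
  // ox..oz: point on the inside; orient the normal away from it
  if (a == b || b == c || a == c) return;
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - ox;
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - oy;
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - oz;
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dim, double level,
                       NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double o0 = origin[0], o1 = origin[1], o2 = origin[2];
  MTState st;
  // cube corner offsets (standard ordering)
  static const int cofs[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tet decomposition around diagonal 0-6
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  double px[8], py[8], pz[8], fv[8];
  uint64_t gi[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + cofs[c][0], jj = j + cofs[c][1], kk = k + cofs[c][2];
          R_xlen_t idx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          fv[c] = field[idx];
          gi[c] = (uint64_t)idx;
          px[c] = o0 + ii * sx; py[c] = o1 + jj * sy; pz[c] = o2 + kk * sz;
          if (fv[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int vid[4] = {a, b, c, d};
          int ins[4], outs[4]; int nin = 0, nout = 0;
          for (int q = 0; q < 4; ++q) {
            if (fv[vid[q]] >= level) ins[nin++] = vid[q];
            else outs[nout++] = vid[q];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int others[3]; int no = 0;
            for (int q = 0; q < 4; ++q)
              if (vid[q] != apex) others[no++] = vid[q];
            int e0 = edge_point(st, gi[apex], gi[others[0]],
                                px[apex], py[apex], pz[apex], fv[apex],
                                px[others[0]], py[others[0]], pz[others[0]],
                                fv[others[0]], level);
            int e1 = edge_point(st, gi[apex], gi[others[1]],
                                px[apex], py[apex], pz[apex], fv[apex],
                                px[others[1]], py[others[1]], pz[others[1]],
                                fv[others[1]], level);
            int e2 = edge_point(st, gi[apex], gi[others[2]],
                                px[apex], py[apex], pz[apex], fv[apex],
                                px[others[2]], py[others[2]], pz[others[2]],
                                fv[others[2]], level);
            // inside reference point = centroid of inside corners
            double ox, oy, oz;
            if (nin == 1) { ox = px[apex]; oy = py[apex]; oz = pz[apex]; }
            else {
              ox = (px[ins[0]] + px[ins[1]] + px[ins[2]]) / 3.0;
              oy = (py[ins[0]] + py[ins[1]] + py[ins[2]]) / 3.0;
              oz = (pz[ins[0]] + pz[ins[1]] + pz[ins[2]]) / 3.0;
            }
            emit_tri(st, e0, e1, e2, ox, oy, oz);
          } else { // 2 in, 2 out -> quad
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eAC = edge_point(st, gi[A], gi[C], px[A], py[A], pz[A], fv[A],
                                 px[C], py[C], pz[C], fv[C], level);
            int eAD = edge_point(st, gi[A], gi[D], px[A], py[A], pz[A], fv[A],
                                 px[D], py[D], pz[D], fv[D], level);
            int eBC = edge_point(st, gi[B], gi[C], px[B], py[B], pz[B], fv[B],
                                 px[C], py[C], pz[C], fv[C], level);
            int eBD = edge_point(st, gi[B], gi[D], px[B], py[B], pz[B], fv[B],
                                 px[D], py[D], pz[D], fv[D], level);
            double ox = (px[A] + px[B]) / 2.0, oy = (py[A] + py[B]) / 2.0,
                   oz = (pz[A] + pz[B]) / 2.0;
            emit_tri(st, eAC, eAD, eBD, ox, oy, oz);
            emit_tri(st, eAC, eBD, eBC, ox, oy, oz);
          }
        }
      }

  const int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = st.f0[f] + 1; F(f, 1) = st.f1[f] + 1; F(f, 2) = st.f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
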