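// Voxel and mesh kernels: 3D connected-component labelling, iso-surface
// extraction by marching tetrahedra, grid-accelerated nearest neighbours,
// segment-mesh intersection, and box morphology. These are the inner loops
// of the segmentation, surface-modelling and registration stages.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Neighbour offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int>& di,
                              std::vector<int>& dj,
                              std::vector<int>& dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cf_label_components(IntegerVector mask, IntegerVector dims,
                                  int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        if (mask[p] == 0 || lab[p] != 0) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int qi = q % n1, qj = (q / n1) % n2, qk = q / (n1 * n2);
          for (size_t t = 0; t < di.size(); ++t) {
            int ii = qi + di[t], jj = qj + dj[t], kk = qk + dk[t];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            int r = idx3(ii, jj, kk, n1, n2);
            if (mask[r] != 0 && lab[r] == 0) {
              lab[r] = next;
              stack.push_back(r);
            }
          }
        }
      }
  return lab;
}

// ---- marching tetrahedra -------------------------------------------------
// Each cube is split into six tetrahedra around the main diagonal
// (0,0,0)-(1,1,1); the decomposition is identical in every cube so shared
// cube faces carry matching face diagonals and the mesh closes watertight.
// Vertices sit on grid edges and are deduplicated by their edge key.

struct EdgeKey {
  int64_t a, b;
  bool operator<(const EdgeKey& o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// [[Rcpp::export]]
List cf_march_tets(NumericVector field, IntegerVector dims, double level) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (field.size() != (R_xlen_t)n1 * n2 * n3)
    stop("field length does not match dims");
  // cube corner offsets, bit order (x, y, z)
  const int cx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  std::map<EdgeKey, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto edge_point = [&](int ga, int gb, double fa, double fb) -> int {
    if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); }
    EdgeKey key{ga, gb};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (!R_finite(t)) t = 0.5;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int ai = ga % n1, aj = (ga / n1) % n2, ak = ga / (n1 * n2);
    int bi = gb % n1, bj = (gb / n1) % n2, bk = gb / (n1 * n2);
    vx.push_back(ai + t * (bi - ai));
    vy.push_back(aj + t * (bj - aj));
    vz.push_back(ak + t * (bk - ak));
    int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  auto add_tri = [&](int a, int b, int c,
                     double ox, double oy, double oz) {
    // orient so the normal points along (ox,oy,oz): inside -> outside
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    if (nx * ox + ny * oy + nz * oz < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  int gidx[8];
  double gf[8];
  double px[8], py[8], pz[8];
  for (int k = 0; k < n3 - 1; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + cx[c], jj = j + cy[c], kk = k + cz[c];
          gidx[c] = idx3(ii, jj, kk, n1, n2);
          gf[c] = field[gidx[c]];
          px[c] = ii; py[c] = jj; pz[c] = kk;
          (gf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vid[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            vid[c] = tets[t][c];
            in[c] = gf[vid[c]] > level;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // centroid difference outside-inside for orientation
          double ix = 0, iy = 0, iz = 0, oxx = 0, oyy = 0, ozz = 0;
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int v = vid[c];
            if (in[c]) { ix += px[v]; iy += py[v]; iz += pz[v]; ++ni; }
            else { oxx += px[v]; oyy += py[v]; ozz += pz[v]; ++no; }
          }
          double ox = oxx / no - ix / ni;
          double oy = oyy / no - iy / ni;
          double oz = ozz / no - iz / ni;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) apex = c;
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != apex) others[m++] = c;
            int e0 = edge_point(gidx[vid[apex]], gidx[vid[others[0]]],
                                gf[vid[apex]], gf[vid[others[0]]]);
            int e1 = edge_point(gidx[vid[apex]], gidx[vid[others[1]]],
                                gf[vid[apex]], gf[vid[others[1]]]);
            int e2 = edge_point(gidx[vid[apex]], gidx[vid[others[2]]],
                                gf[vid[apex]], gf[vid[others[2]]]);
            add_tri(e0, e1, e2, ox, oy, oz);
          } else {
            int ina[2], outa[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c)
              (in[c] ? ina[mi++] : outa[mo++]) = c;
            int eAC = edge_point(gidx[vid[ina[0]]], gidx[vid[outa[0]]],
                                 gf[vid[ina[0]]], gf[vid[outa[0]]]);
            int eAD = edge_point(gidx[vid[ina[0]]], gidx[vid[outa[1]]],
                                 gf[vid[ina[0]]], gf[vid[outa[1]]]);
            int eBD = edge_point(gidx[vid[ina[1]]], gidx[vid[outa[1]]],
                                 gf[vid[ina[1]]], gf[vid[outa[1]]]);
            int eBC = edge_point(gidx[vid[ina[1]]], gidx[vid[outa[0]]],
                                 gf[vid[ina[1]]], gf[vid[outa[0]]]);
            add_tri(eAC, eAD, eBD, ox, oy, oz);
            add_tri(eAC, eBD, eBC, ox, oy, oz);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = f0[f] + 1; F(f, 1) = f1[f] + 1; F(f, 2) = f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- nearest neighbours --------------------------------------------------
// Uniform hash grid over the reference points; queries expand outward shell
// by shell until the current best distance cannot be beaten.

// [[Rcpp::export]]
IntegerVector cf_nearest_neighbour(NumericMatrix query, NumericMatrix ref,
                                   double cell) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < nr; ++i) {
      if (ref(i, d) < lo[d]) lo[d] = ref(i, d);
      if (ref(i, d) > hi[d]) hi[d] = ref(i, d);
    }
  }
  if (!(cell > 0)) cell = 1.0;
  int nb[3];
  for (int d = 0; d < 3; ++d) {
    nb[d] = (int)std::floor((hi[d] - lo[d]) / cell) + 1;
    if (nb[d] < 1) nb[d] = 1;
  }
  std::vector<std::vector<int> > buckets((size_t)nb[0] * nb[1] * nb[2]);
  auto bucket_of = [&](double x, double y, double z) -> int {
    int bx = (int)std::floor((x - lo[0]) / cell);
    int by = (int)std::floor((y - lo[1]) / cell);
    int bz = (int)std::floor((z - lo[2]) / cell);
    bx = std::max(0, std::min(nb[0] - 1, bx));
    by = std::max(0, std::min(nb[1] - 1, by));
    bz = std::max(0, std::min(nb[2] - 1, bz));
    return bx + nb[0] * (by + nb[1] * bz);
  };
  for (int i = 0; i < nr; ++i)
    buckets[bucket_of(ref(i, 0), ref(i, 1), ref(i, 2))].push_back(i);

  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    int bx = std::max(0, std::min(nb[0] - 1,
              (int)std::floor((x - lo[0]) / cell)));
    int by = std::max(0, std::min(nb[1] - 1,
              (int)std::floor((y - lo[1]) / cell)));
    int bz = std::max(0, std::min(nb[2] - 1,
              (int)std::floor((z - lo[2]) / cell)));
    double best = R_PosInf;
    int besti = -1;
    int max_ring = std::max(nb[0], std::max(nb[1], nb[2]));
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (besti >= 0 && (double)(ring - 1) * cell > std::sqrt(best)) break;
      bool visited_any = false;
      for (int a = bx - ring; a <= bx + ring; ++a) {
        if (a < 0 || a >= nb[0]) continue;
        for (int b = by - ring; b <= by + ring; ++b) {
          if (b < 0 || b >= nb[1]) continue;
          for (int c = bz - ring; c <= bz + ring; ++c) {
            if (c < 0 || c >= nb[2]) continue;
            if (std::max(std::abs(a - bx),
                std::max(std::abs(b - by), std::abs(c - bz))) != ring)
              continue;
            visited_any = true;
            const std::vector<int>& bk =
              buckets[a + nb[0] * (b + nb[1] * c)];
            for (size_t t = 0; t < bk.size(); ++t) {
              int i = bk[t];
              double dx = ref(i, 0) - x, dy = ref(i, 1) - y,
                     dz = ref(i, 2) - z;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = i; }
            }
          }
        }
      }
      if (!visited_any && besti >= 0) break;
    }
    out[q] = besti + 1;
  }
  return out;
}

// ---- segment vs triangle mesh -------------------------------------------
// Moller-Trumbore; counts triangles intersected by the closed segment p0-p1.

// [[Rcpp::export]]
int cf_segment_mesh_hits(NumericVector p0, NumericVector p1,
                         NumericMatrix V, IntegerMatrix F) {
  const double eps = 1e-12;
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  int hits = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1),
           e1z = V(b, 2) - V(a, 2);
    double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1),
           e2z = V(c, 2) - V(a, 2);
    double hx = dy * e2z - dz * e2y;
    double hy = dz * e2x - dx * e2z;
    double hz = dx * e2y - dy * e2x;
    double det = e1x * hx + e1y * hy + e1z * hz;
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    double sx = p0[0] - V(a, 0), sy = p0[1] - V(a, 1), sz = p0[2] - V(a, 2);
    double u = (sx * hx + sy * hy + sz * hz) * inv;
    if (u < 0.0 || u > 1.0) continue;
    double qx = sy * e1z - sz * e1y;
    double qy = sz * e1x - sx * e1z;
    double qz = sx * e1y - sy * e1x;
    double v = (dx * qx + dy * qy + dz * qz) * inv;
    if (v < 0.0 || u + v > 1.0) continue;
    double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
    if (t >= 0.0 && t <= 1.0) ++hits;
  }
  return hits;
}

// ---- box morphology ------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cf_box_morph(IntegerVector mask, IntegerVector dims, int r,
                           bool dilate) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector cur = clone(mask);
  // separable: run a 1D max (or min) filter along each axis
  for (int axis = 0; axis < 3; ++axis) {
    IntegerVector nxt(cur.size());
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int val = dilate ? 0 : 1;
          for (int o = -r; o <= r; ++o) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii += o;
            else if (axis == 1) jj += o;
            else kk += o;
            int s;
            if (ii < 0 || jj < 0 || kk < 0 ||
                ii >= n1 || jj >= n2 || kk >= n3)
              s = 0;
            else
              s = cur[idx3(ii, jj, kk, n1, n2)];
            if (dilate) { if (s) { val = 1; break; } }
            else { if (!s) { val = 0; break; } }
          }
          nxt[idx3(i, j, k, n1, n2)] = val;
        }
    cur = nxt;
  }
  return cur;
}
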