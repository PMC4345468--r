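// Low-level 3D geometry kernels: incremental convex hull, connected-component
// labelling on voxel grids, and brute-force nearest-point assignment.
#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;          // vertex indices (0-based)
  double nx, ny, nz, d; // outward normal, plane offset (n . x = d)
  bool alive;
};

inline void face_plane(Face &f, const NumericMatrix &P, double ix, double iy,
                       double iz) {
  double ax = P(f.a, 0), ay = P(f.a, 1), az = P(f.a, 2);
  double ux = P(f.b, 0) - ax, uy = P(f.b, 1) - ay, uz = P(f.b, 2) - az;
  double vx = P(f.c, 0) - ax, vy = P(f.c, 1) - ay, vz = P(f.c, 2) - az;
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double len = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (len > 0) { nx /= len; ny /= len; nz /= len; }
  double d = nx * ax + ny * ay + nz * az;
  // orient away from the interior reference point
  if (nx * ix + ny * iy + nz * iz > d) {
    std::swap(f.b, f.c);
    nx = -nx; ny = -ny; nz = -nz; d = -d;
  }
  f.nx = nx; f.ny = ny; f.nz = nz; f.d = d;
}

inline double face_dist(const Face &f, const NumericMatrix &P, int p) {
  return f.nx * P(p, 0) + f.ny * P(p, 1) + f.nz * P(p, 2) - f.d;
}

} // namespace

// Incremental 3D convex hull of an n x 3 point matrix.
// Returns list(vertices = indices (1-based) of hull vertices,
//              faces = m x 3 matrix of 1-based indices into the input,
//              normals = m x 3 outward unit normals, offsets = m).
// Coplanar points within tolerance of an existing facet plane are treated as
// interior; callers use tolerance-based containment tests downstream.
// [[Rcpp::export]]
List convex_hull3_cpp(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  // scale-dependent tolerance
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (P(i, k) < lo[k]) lo[k] = P(i, k);
      if (P(i, k) > hi[k]) hi[k] = P(i, k);
    }
  double diag = 0;
  for (int k = 0; k < 3; ++k) diag += (hi[k] - lo[k]) * (hi[k] - lo[k]);
  diag = std::sqrt(diag);
  if (diag <= 0) stop("degenerate point set (all points identical)");
  double eps = 1e-9 * diag;

  // initial simplex: two extreme points, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  double best = -1;
  for (int k = 0; k < 3; ++k) {
    int a = 0, b = 0;
    for (int i = 1; i < n; ++i) {
      if (P(i, k) < P(a, k)) a = i;
      if (P(i, k) > P(b, k)) b = i;
    }
    double dx = P(a, 0) - P(b, 0), dy = P(a, 1) - P(b, 1), dz = P(a, 2) - P(b, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; i0 = a; i1 = b; }
  }
  if (best <= eps * eps) stop("degenerate point set (all points identical)");
  double ex = P(i1, 0) - P(i0, 0), ey = P(i1, 1) - P(i0, 1), ez = P(i1, 2) - P(i0, 2);
  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double wx = P(i, 0) - P(i0, 0), wy = P(i, 1) - P(i0, 1), wz = P(i, 2) - P(i0, 2);
    double cx = ey * wz - ez * wy, cy = ez * wx - ex * wz, cz = ex * wy - ey * wx;
    double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (std::sqrt(best) / std::sqrt(ex * ex + ey * ey + ez * ez) <= eps)
    stop("degenerate point set (collinear)");
  // plane through i0,i1,i2
  double ux = P(i1, 0) - P(i0, 0), uy = P(i1, 1) - P(i0, 1), uz = P(i1, 2) - P(i0, 2);
  double vx = P(i2, 0) - P(i0, 0), vy = P(i2, 1) - P(i0, 1), vz = P(i2, 2) - P(i0, 2);
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  double nlen = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nlen; ny /= nlen; nz /= nlen;
  double d0 = nx * P(i0, 0) + ny * P(i0, 1) + nz * P(i0, 2);
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(nx * P(i, 0) + ny * P(i, 1) + nz * P(i, 2) - d0);
    if (h > best) { best = h; i3 = i; }
  }
  if (best <= eps) stop("degenerate point set (coplanar)");

  double ix = (P(i0, 0) + P(i1, 0) + P(i2, 0) + P(i3, 0)) / 4.0;
  double iy = (P(i0, 1) + P(i1, 1) + P(i2, 1) + P(i3, 1)) / 4.0;
  double iz = (P(i0, 2) + P(i1, 2) + P(i2, 2) + P(i3, 2)) / 4.0;

  std::vector<Face> faces;
  int tet[4] = { i0, i1, i2, i3 };
  int tri[4][3] = { {0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3} };
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = tet[tri[t][0]]; f.b = tet[tri[t][1]]; f.c = tet[tri[t][2]];
    f.alive = true;
    face_plane(f, P, ix, iy, iz);
    faces.push_back(f);
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t fi = 0; fi < faces.size(); ++fi)
      if (faces[fi].alive && face_dist(faces[fi], P, p) > eps)
        vis.push_back((int)fi);
    if (vis.empty()) continue;

    // horizon: edges of visible faces shared with a non-visible (or no) face
    std::map<std::pair<int, int>, int> ecount;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face &f = faces[vis[k]];
      int e[3][2] = { {f.a, f.b}, {f.b, f.c}, {f.c, f.a} };
      for (int t = 0; t < 3; ++t) {
        int a = e[t][0], b = e[t][1];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        ecount[key]++;
      }
    }
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue; // interior edge of the visible region
      Face f; f.a = it->first.first; f.b = it->first.second; f.c = p;
      f.alive = true;
      face_plane(f, P, ix, iy, iz);
      faces.push_back(f);
    }
    used[p] = true;
  }

  int m = 0;
  for (size_t fi = 0; fi < faces.size(); ++fi) if (faces[fi].alive) ++m;
  IntegerMatrix F(m, 3);
  NumericMatrix N(m, 3);
  NumericVector D(m);
  std::vector<bool> isvert(n, false);
  int r = 0;
  for (size_t fi = 0; fi < faces.size(); ++fi) {
    if (!faces[fi].alive) continue;
    const Face &f = faces[fi];
    F(r, 0) = f.a + 1; F(r, 1) = f.b + 1; F(r, 2) = f.c + 1;
    N(r, 0) = f.nx; N(r, 1) = f.ny; N(r, 2) = f.nz;
    D[r] = f.d;
    isvert[f.a] = isvert[f.b] = isvert[f.c] = true;
    ++r;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (isvert[i]) verts.push_back(i + 1);
  return List::create(_["vertices"] = wrap(verts), _["faces"] = F,
                      _["normals"] = N, _["offsets"] = D);
}

// Connected-component labelling of a 3D logical array (dim nz, ny, nx) under
// 6/18/26-connectivity. Returns an integer array of labels (0 = background),
// labelled in first-encounter order (deterministic).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dzs, dys, dxs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }

  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < (int)mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int k = cur % nz, rest = cur / nz;
      int j = rest % ny, ii = rest / ny;
      for (size_t t = 0; t < dzs.size(); ++t) {
        int kk = k + dzs[t], jj = j + dys[t], iii = ii + dxs[t];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || iii < 0 || iii >= nx)
          continue;
        int idx = kk + nz * (jj + ny * iii);
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; stack.push_back(idx); }
      }
    }
  }
  return lab;
}

// For each query row (m x 3) return the 1-based index of the nearest point in
// pts (n x 3); exact ties resolved to the lowest point index.
// [[Rcpp::export]]
IntegerVector nearest_point_cpp(NumericMatrix queries, NumericMatrix pts) {
  int m = queries.nrow(), n = pts.nrow();
  if (n < 1) stop("need at least one point");
  IntegerVector out(m);
  for (int q = 0; q < m; ++q) {
    double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    double bd = R_PosInf; int bi = 0;
    for (int p = 0; p < n; ++p) {
      double dx = pts(p, 0) - qx, dy = pts(p, 1) - qy, dz = pts(p, 2) - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bd) { bd = d2; bi = p; }
    }
    out[q] = bi + 1;
  }
  return out;
}

// Threshold-free cluster enhancement of a non-negative excess map:
// statistic(v) = sum over thresholds h of vol(component of {excess >= h}
// containing v)^E * h^H * dh. Thresholds descend; a union-find grows the
// supra-threshold sets incrementally, so the whole integral is one pass.
namespace {
int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}
} // namespace

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector excess, int connectivity, double E,
                       double H, double dh, double voxvol) {
  IntegerVector dim = excess.attr("dim");
  if (dim.size() != 3) stop("excess must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = excess.size();
  NumericVector stat(n, 0.0);
  stat.attr("dim") = dim;
  double mx = 0;
  for (int i = 0; i < n; ++i) if (excess[i] > mx) mx = excess[i];
  if (mx <= 0 || dh <= 0) return stat;

  std::vector<int> dzs, dys, dxs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }

  // voxels sorted by excess descending (only positive ones matter)
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (excess[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return excess[a] > excess[b]; });

  std::vector<int> par(n, -1), csize(n, 0);
  std::vector<char> active(n, 0);
  size_t pos = 0;
  int nsteps = (int)std::ceil(mx / dh);
  std::vector<int> active_list;
  for (int s = nsteps; s >= 1; --s) {
    double h = s * dh;
    // activate voxels with excess >= h
    while (pos < order.size() && excess[order[pos]] >= h) {
      int v = order[pos++];
      par[v] = v; csize[v] = 1; active[v] = 1;
      active_list.push_back(v);
      int k = v % nz, rest = v / nz;
      int j = rest % ny, ii = rest / ny;
      for (size_t t = 0; t < dzs.size(); ++t) {
        int kk = k + dzs[t], jj = j + dys[t], iii = ii + dxs[t];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || iii < 0 || iii >= nx)
          continue;
        int u = kk + nz * (jj + ny * iii);
        if (!active[u]) continue;
        int ra = uf_find(par, v), rb = uf_find(par, u);
        if (ra != rb) {
          if (csize[ra] < csize[rb]) std::swap(ra, rb);
          par[rb] = ra;
          csize[ra] += csize[rb];
        }
      }
    }
    // accumulate this threshold's contribution (E = 0.5 is the common
    // default; sqrt is much cheaper than pow)
    double hH = std::pow(h, H) * dh;
    bool half = std::fabs(E - 0.5) < 1e-12;
    for (size_t t = 0; t < active_list.size(); ++t) {
      int v = active_list[t];
      double vol = csize[uf_find(par, v)] * voxvol;
      stat[v] += (half ? std::sqrt(vol) : std::pow(vol, E)) * hH;
    }
  }
  return stat;
}
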