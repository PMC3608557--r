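#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>

// Voxel grids arrive as R logical arrays with dim = c(ny, nx, nz):
// linear index = i + ny * (j + nx * k), 0-based, i = row (y), j = col (x),
// k = slice (z).  Cartesian slice orientations are encoded by the axis that
// is held fixed: axis 3 -> xy slices, axis 1 -> xz slices, axis 2 -> yz
// slices.

using namespace Rcpp;

static inline int lidx(int i, int j, int k, int ny, int nx) {
  return i + ny * (j + nx * k);
}

// 3D connected-component labeling, 26- or 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector vol, IntegerVector dim, int connectivity) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = vol.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  int next = 0;
  std::queue<int> q;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < nx; ++j) for (int i = 0; i < ny; ++i) {
    int v = lidx(i, j, k, ny, nx);
    if (!vol[v] || labels[v]) continue;
    labels[v] = ++next;
    q.push(v);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int ci = c % ny, cj = (c / ny) % nx, ck = c / (ny * nx);
      for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        if (connectivity == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1) continue;
        int ii = ci + di, jj = cj + dj, kk = ck + dk;
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz) continue;
        int w = lidx(ii, jj, kk, ny, nx);
        if (vol[w] && !labels[w]) { labels[w] = next; q.push(w); }
      }
    }
  }
  return labels;
}

// Map a slice coordinate system onto the volume: the slice runs over the two
// free dimensions (u, v); `axis` (1 = y fixed, 2 = x fixed, 3 = z fixed)
// selects the orientation.
static inline int slice_lidx(int axis, int s, int u, int v, int ny, int nx) {
  switch (axis) {
  case 1:  return lidx(s, u, v, ny, nx);  // xz slice: u = x, v = z
  case 2:  return lidx(u, s, v, ny, nx);  // yz slice: u = y, v = z
  default: return lidx(u, v, s, ny, nx);  // xy slice: u = y, v = x
  }
}

static void slice_extents(int axis, const IntegerVector& dim, int& ns, int& nu, int& nv) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  if (axis == 1)      { ns = ny; nu = nx; nv = nz; }
  else if (axis == 2) { ns = nx; nu = ny; nv = nz; }
  else                { ns = nz; nu = ny; nv = nx; }
}

// Per-voxel area (in pixels) of the 2D 8-connected component containing the
// voxel, in the slices perpendicular to `axis`. Background voxels get 0.
// [[Rcpp::export]]
IntegerVector cpp_slice_areas(LogicalVector vol, IntegerVector dim, int axis) {
  const int ny = dim[0], nx = dim[1];
  int ns, nu, nv;
  slice_extents(axis, dim, ns, nu, nv);
  IntegerVector areas(vol.size(), 0);
  areas.attr("dim") = dim;
  std::vector<int> lab(static_cast<size_t>(nu) * nv);
  std::vector<int> stack;
  for (int s = 0; s < ns; ++s) {
    std::fill(lab.begin(), lab.end(), 0);
    int next = 0;
    std::vector<int> area_of(1, 0);
    std::vector<std::vector<int> > members(1);
    for (int v = 0; v < nv; ++v) for (int u = 0; u < nu; ++u) {
      int p = u + nu * v;
      if (!vol[slice_lidx(axis, s, u, v, ny, nx)] || lab[p]) continue;
      ++next;
      area_of.push_back(0);
      members.push_back(std::vector<int>());
      lab[p] = next;
      stack.clear();
      stack.push_back(p);
      while (!stack.empty()) {
        int c = stack.back(); stack.pop_back();
        members[next].push_back(c);
        ++area_of[next];
        int cu = c % nu, cv = c / nu;
        for (int dv = -1; dv <= 1; ++dv) for (int du = -1; du <= 1; ++du) {
          if (!du && !dv) continue;
          int uu = cu + du, vv = cv + dv;
          if (uu < 0 || uu >= nu || vv < 0 || vv >= nv) continue;
          int pp = uu + nu * vv;
          if (!lab[pp] && vol[slice_lidx(axis, s, uu, vv, ny, nx)]) {
            lab[pp] = next;
            stack.push_back(pp);
          }
        }
      }
    }
    for (int comp = 1; comp <= next; ++comp)
      for (size_t m = 0; m < members[comp].size(); ++m) {
        int p = members[comp][m];
        areas[slice_lidx(axis, s, p % nu, p / nu, ny, nx)] = area_of[comp];
      }
  }
  return areas;
}

// Fill 2D holes slice-wise (background 4-connectivity, complement of
// foreground 8-connectivity) in the slices perpendicular to `axis`.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector vol, IntegerVector dim, int axis) {
  const int ny = dim[0], nx = dim[1];
  int ns, nu, nv;
  slice_extents(axis, dim, ns, nu, nv);
  LogicalVector out = clone(vol);
  out.attr("dim") = dim;
  std::vector<char> outside(static_cast<size_t>(nu) * nv);
  std::vector<int> stack;
  for (int s = 0; s < ns; ++s) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    // seed from every background pixel on the slice border
    for (int u = 0; u < nu; ++u) for (int v = 0; v < nv; ++v) {
      if (u != 0 && u != nu - 1 && v != 0 && v != nv - 1) continue;
      int p = u + nu * v;
      if (!vol[slice_lidx(axis, s, u, v, ny, nx)] && !outside[p]) {
        outside[p] = 1;
        stack.push_back(p);
      }
    }
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cu = c % nu, cv = c / nu;
      const int du4[4] = {1, -1, 0, 0}, dv4[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int uu = cu + du4[t], vv = cv + dv4[t];
        if (uu < 0 || uu >= nu || vv < 0 || vv >= nv) continue;
        int pp = uu + nu * vv;
        if (!outside[pp] && !vol[slice_lidx(axis, s, uu, vv, ny, nx)]) {
          outside[pp] = 1;
          stack.push_back(pp);
        }
      }
    }
    for (int v = 0; v < nv; ++v) for (int u = 0; u < nu; ++u) {
      int p = u + nu * v;
      if (!outside[p]) out[slice_lidx(axis, s, u, v, ny, nx)] = true;
    }
  }
  return out;
}

// ---- topology-preserving 3D thinning --------------------------------------
//
// Directional border thinning in the Lee decision-tree family: in each pass,
// border voxels of one of the six face directions that are simple points (in
// the (26, 6) digital topology) and not curve endpoints are collected, then
// deleted sequentially with the simplicity test re-evaluated at deletion
// time. Simplicity uses the Malandain-Bertrand characterization: exactly one
// 26-component of foreground in the 26-neighborhood, and exactly one
// 6-component of background in the 18-neighborhood that is 6-adjacent to the
// center.

struct Cube27 {
  bool v[27]; // (di+1) + 3*(dj+1) + 9*(dk+1)
};

static inline int coff(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

static void load_cube(const std::vector<char>& vol, int i, int j, int k,
                      int ny, int nx, int nz, Cube27& c) {
  for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
    int ii = i + di, jj = j + dj, kk = k + dk;
    bool in = ii >= 0 && ii < ny && jj >= 0 && jj < nx && kk >= 0 && kk < nz;
    c.v[coff(di, dj, dk)] = in && vol[lidx(ii, jj, kk, ny, nx)];
  }
}

static int fg_neighbor_count(const Cube27& c) {
  int n = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && c.v[t]) ++n;
  return n;
}

// number of 26-connected components of foreground among the 26 neighbors
static int n26_components(const Cube27& c) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27], top;
  for (int start = 0; start < 27; ++start) {
    if (start == 13 || !c.v[start] || seen[start]) continue;
    ++comps;
    top = 0; stack[top++] = start; seen[start] = true;
    while (top) {
      int t = stack[--top];
      int ti = t % 3 - 1, tj = (t / 3) % 3 - 1, tk = t / 9 - 1;
      for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        int ni = ti + di, nj = tj + dj, nk = tk + dk;
        if (ni < -1 || ni > 1 || nj < -1 || nj > 1 || nk < -1 || nk > 1) continue;
        int u = coff(ni, nj, nk);
        if (u == 13 || u == t || seen[u] || !c.v[u]) continue;
        seen[u] = true;
        stack[top++] = u;
      }
    }
  }
  return comps;
}

// number of 6-connected components of background within the 18-neighborhood
// that contain at least one face neighbor of the center
static int n6_bg_components(const Cube27& c) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27], top;
  for (int si = -1; si <= 1; ++si) for (int sj = -1; sj <= 1; ++sj) for (int sk = -1; sk <= 1; ++sk) {
    // seeds: the six face neighbors
    if (std::abs(si) + std::abs(sj) + std::abs(sk) != 1) continue;
    int start = coff(si, sj, sk);
    if (c.v[start] || seen[start]) continue;
    ++comps;
    top = 0; stack[top++] = start; seen[start] = true;
    while (top) {
      int t = stack[--top];
      int ti = t % 3 - 1, tj = (t / 3) % 3 - 1, tk = t / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int e = 0; e < 6; ++e) {
        int ni = ti + d6[e][0], nj = tj + d6[e][1], nk = tk + d6[e][2];
        if (ni < -1 || ni > 1 || nj < -1 || nj > 1 || nk < -1 || nk > 1) continue;
        if (std::abs(ni) + std::abs(nj) + std::abs(nk) > 2) continue; // stay in N18
        int u = coff(ni, nj, nk);
        if (u == 13 || seen[u] || c.v[u]) continue;
        seen[u] = true;
        stack[top++] = u;
      }
    }
  }
  return comps;
}

static bool is_simple(const Cube27& c) {
  return n26_components(c) == 1 && n6_bg_components(c) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector vol, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = vol.size();
  std::vector<char> w(n);
  for (R_xlen_t t = 0; t < n; ++t) w[t] = vol[t] ? 1 : 0;
  const int dirs[6][3] = {
    {0, 0, 1}, {0, 0, -1}, {-1, 0, 0}, {1, 0, 0}, {0, -1, 0}, {0, 1, 0}
  };
  Cube27 c;
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k) for (int j = 0; j < nx; ++j) for (int i = 0; i < ny; ++i) {
        int v = lidx(i, j, k, ny, nx);
        if (!w[v]) continue;
        int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
        bool border = !(ii >= 0 && ii < ny && jj >= 0 && jj < nx && kk >= 0 && kk < nz) ||
                      !w[lidx(ii, jj, kk, ny, nx)];
        if (!border) continue;
        load_cube(w, i, j, k, ny, nx, nz, c);
        int nb = fg_neighbor_count(c);
        if (nb <= 1) continue; // endpoint or isolated voxel: keep
        if (is_simple(c)) cand.push_back(v);
      }
      // sequential deletion with re-check preserves topology exactly
      for (size_t t = 0; t < cand.size(); ++t) {
        int v = cand[t];
        int i = v % ny, j = (v / ny) % nx, k = v / (ny * nx);
        load_cube(w, i, j, k, ny, nx, nz, c);
        if (fg_neighbor_count(c) <= 1) continue;
        if (!is_simple(c)) continue;
        w[v] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = w[t] != 0;
  out.attr("dim") = dim;
  return out;
}
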