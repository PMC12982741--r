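#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3-D arrays arrive as R column-major vectors with an explicit dim triple.
// Gray-level grids use 0 = outside the mask, 1..G inside.

static inline int lin(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

static inline bool inside(int x, int y, int z, const int* d) {
  return x >= 0 && y >= 0 && z >= 0 && x < d[0] && y < d[1] && z < d[2];
}

// [[Rcpp::export]]
IntegerVector cpp_erode6(IntegerVector mask, IntegerVector dim) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  IntegerVector out(mask.size());
  const int off[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        const int i = lin(x, y, z, d);
        if (!mask[i]) { out[i] = 0; continue; }
        bool keep = true;
        for (int n = 0; n < 6 && keep; ++n) {
          const int nx = x + off[n][0], ny = y + off[n][1], nz = z + off[n][2];
          // out-of-grid counts as background
          if (!inside(nx, ny, nz, d) || !mask[lin(nx, ny, nz, d)]) keep = false;
        }
        out[i] = keep ? 1 : 0;
      }
  return out;
}

// connected-component labeling, 26-connectivity (conn = 26) or 6 (conn = 6)
// [[Rcpp::export]]
IntegerVector cpp_label(IntegerVector mask, IntegerVector dim, int conn) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int n = mask.size();
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      const int cx = cur % d[0], cy = (cur / d[0]) % d[1], cz = cur / (d[0] * d[1]);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (conn == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            const int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (!inside(nx, ny, nz, d)) continue;
            const int ni = lin(nx, ny, nz, d);
            if (mask[ni] && !lab[ni]) { lab[ni] = next; stack.push_back(ni); }
          }
    }
  }
  return lab;
}

// per-offset co-occurrence counts (directed; caller symmetrizes / averages)
// [[Rcpp::export]]
List cpp_glcm(IntegerVector levels, IntegerVector dim, IntegerMatrix offsets, int G) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  List out(offsets.nrow());
  for (int o = 0; o < offsets.nrow(); ++o) {
    NumericMatrix C(G, G);
    const int ox = offsets(o, 0), oy = offsets(o, 1), oz = offsets(o, 2);
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const int g1 = levels[lin(x, y, z, d)];
          if (!g1) continue;
          const int nx = x + ox, ny = y + oy, nz = z + oz;
          if (!inside(nx, ny, nz, d)) continue;
          const int g2 = levels[lin(nx, ny, nz, d)];
          if (!g2) continue;
          C(g1 - 1, g2 - 1) += 1.0;
        }
    out[o] = C;
  }
  return out;
}

// run-length matrices, one G x maxRunLength matrix per direction
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dim, IntegerMatrix dirs, int G) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int maxlen = std::max(d[0], std::max(d[1], d[2]));
  List out(dirs.nrow());
  for (int o = 0; o < dirs.nrow(); ++o) {
    NumericMatrix R(G, maxlen);
    const int ox = dirs(o, 0), oy = dirs(o, 1), oz = dirs(o, 2);
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const int g = levels[lin(x, y, z, d)];
          if (!g) continue;
          // run starts here iff the previous voxel along the direction differs
          const int px = x - ox, py = y - oy, pz = z - oz;
          if (inside(px, py, pz, d) && levels[lin(px, py, pz, d)] == g) continue;
          int len = 1;
          int nx = x + ox, ny = y + oy, nz = z + oz;
          while (inside(nx, ny, nz, d) && levels[lin(nx, ny, nz, d)] == g) {
            ++len; nx += ox; ny += oy; nz += oz;
          }
          R(g - 1, len - 1) += 1.0;
        }
    out[o] = R;
  }
  return out;
}

// size-zone list: one row (level, size) per 26-connected iso-level zone
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int n = levels.size();
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int i = 0; i < n; ++i) {
    if (!levels[i] || seen[i]) continue;
    const int g = levels[i];
    int size = 0;
    stack.push_back(i); seen[i] = 1;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      ++size;
      const int cx = cur % d[0], cy = (cur / d[0]) % d[1], cz = cur / (d[0] * d[1]);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (!inside(nx, ny, nz, d)) continue;
            const int ni = lin(nx, ny, nz, d);
            if (!seen[ni] && levels[ni] == g) { seen[ni] = 1; stack.push_back(ni); }
          }
    }
    zl.push_back(g); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) { out(r, 0) = zl[r]; out(r, 1) = zs[r]; }
  return out;
}

// neighbouring gray-tone difference: per level, sum |g - mean(26-neighbours)| and count
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int G) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  NumericMatrix out(G, 2); // col 0: s_i, col 1: n_i
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        const int g = levels[lin(x, y, z, d)];
        if (!g) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int nx = x + dx, ny = y + dy, nz = z + dz;
              if (!inside(nx, ny, nz, d)) continue;
              const int ng = levels[lin(nx, ny, nz, d)];
              if (ng) { sum += ng; ++cnt; }
            }
        if (cnt == 0) continue; // isolated voxel contributes nothing
        out(g - 1, 0) += std::abs((double)g - sum / cnt);
        out(g - 1, 1) += 1.0;
      }
  return out;
}

// dependence matrix: counts of (level, number of 26-neighbours within alpha)
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int G, int alpha) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  NumericMatrix out(G, 27); // dependence size 0..26 -> columns 1..27
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        const int g = levels[lin(x, y, z, d)];
        if (!g) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int nx = x + dx, ny = y + dy, nz = z + dz;
              if (!inside(nx, ny, nz, d)) continue;
              const int ng = levels[lin(nx, ny, nz, d)];
              if (ng && std::abs(ng - g) <= alpha) ++dep;
            }
        out(g - 1, dep) += 1.0;
      }
  return out;
}

// separable same-size convolution with zero padding, line-based
// [[Rcpp::export]]
NumericVector cpp_conv3d_sep(NumericVector x, IntegerVector dim, NumericVector kernel) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int kr = (kernel.size() - 1) / 2;
  const double* kc = &kernel[kr]; // centered kernel
  NumericVector a = clone(x), b(x.size());
  std::vector<double> line;
  for (int axis = 0; axis < 3; ++axis) {
    const int len = d[axis];
    line.resize(len);
    int stride, n1, n2, s1, s2;
    if (axis == 0) { stride = 1; n1 = d[1]; n2 = d[2]; s1 = d[0]; s2 = d[0] * d[1]; }
    else if (axis == 1) { stride = d[0]; n1 = d[0]; n2 = d[2]; s1 = 1; s2 = d[0] * d[1]; }
    else { stride = d[0] * d[1]; n1 = d[0]; n2 = d[1]; s1 = 1; s2 = d[0]; }
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        const int base = j1 * s1 + j2 * s2;
        for (int i = 0; i < len; ++i) line[i] = a[base + i * stride];
        for (int i = 0; i < len; ++i) {
          const int lo = std::max(-kr, -i), hi = std::min(kr, len - 1 - i);
          double acc = 0.0;
          const double* src = &line[i];
          for (int t = lo; t <= hi; ++t) acc += kc[t] * src[t];
          b[base + i * stride] = acc;
        }
      }
    std::swap(a, b);
  }
  return a;
}
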