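#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arrays use the package's (z, y, x) axis convention with R's column-major
// layout: linear index = z + nz * (y + ny * x).

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cpp_conv1d_axis")]]
NumericVector cpp_conv1d_axis(NumericVector arr, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const int klen = kernel.size();
  const int kh = klen / 2;  // kernel assumed odd length, centered
  NumericVector out(n);

  int len, stride;
  if (axis == 0)      { len = nz; stride = 1; }
  else if (axis == 1) { len = ny; stride = nz; }
  else                { len = nx; stride = nz * ny; }

  // iterate over all 1D lines along `axis`
  const int n_lines = n / len;
  std::vector<double> line(len), res(len);
  for (int l = 0; l < n_lines; ++l) {
    // compute base offset of this line
    int base;
    if (axis == 0) {
      int y = l % ny, x = l / ny;
      base = idx3(0, y, x, nz, ny);
    } else if (axis == 1) {
      int z = l % nz, x = l / nz;
      base = idx3(z, 0, x, nz, ny);
    } else {
      int z = l % nz, y = l / nz;
      base = idx3(z, y, 0, nz, ny);
    }
    for (int i = 0; i < len; ++i) line[i] = arr[base + i * stride];
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      for (int k = 0; k < klen; ++k) {
        int j = i + k - kh;
        // reflect boundary (symmetric, no repeated edge sample for len > 1)
        while (j < 0 || j >= len) {
          if (j < 0) j = -j - 1;
          if (j >= len) j = 2 * len - j - 1;
        }
        acc += line[j] * kernel[k];
      }
      res[i] = acc;
    }
    for (int i = 0; i < len; ++i) out[base + i * stride] = res[i];
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing w; f holds squared distances, positions are i*w.
static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double pq = q * w, pv = v[k] * w;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double pq = q * w;
    while (zb[k + 1] < pq) ++k;
    double diff = pq - v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
  f = d;
}

// Euclidean distance transform of a foreground mask: distance (in the units
// of `spacing`) from each foreground voxel to the nearest background voxel.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  std::vector<double> line;
  // z axis
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int base = idx3(0, y, x, nz, ny);
      for (int z = 0; z < nz; ++z) line[z] = d[base + z];
      dt1d(line, spacing[0]);
      for (int z = 0; z < nz; ++z) d[base + z] = line[z];
    }
  // y axis
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      int base = idx3(z, 0, x, nz, ny);
      for (int y = 0; y < ny; ++y) line[y] = d[base + y * nz];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + y * nz] = line[y];
    }
  // x axis
  line.resize(nx);
  const int sx = nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      int base = idx3(z, y, 0, nz, ny);
      for (int x = 0; x < nx; ++x) line[x] = d[base + x * sx];
      dt1d(line, spacing[2]);
      for (int x = 0; x < nx; ++x) d[base + x * sx] = line[x];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  return out;
}

// 6-connected component labeling; labels contiguous 1..K.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0] != 0) continue;
    ++next;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Fill interior cavities: any background component not reachable from the
// image border becomes foreground.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z > 0 && z < nz - 1 && y > 0 && y < ny - 1 && x > 0 && x < nx - 1)
          continue;
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    const int dz[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dx[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] && !outside[j]) { outside[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Local maxima (26-neighborhood, >= plateau convention) of `v` restricted to
// `mask`, with v > threshold.
// [[Rcpp::export(name = ".cpp_local_maxima")]]
LogicalVector cpp_local_maxima(NumericVector v, LogicalVector mask,
                               IntegerVector dims, double threshold) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  LogicalVector out(n, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i] || v[i] <= threshold) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; ++dz)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dx = -1; dx <= 1 && is_max; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) continue;
              if (v[idx3(zz, yy, xx, nz, ny)] > v[i]) is_max = false;
            }
        if (is_max) out[i] = 1;
      }
  return out;
}

struct WsItem {
  double prio;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsItem &a, const WsItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-controlled watershed: flood `mask` from labeled markers in order of
// increasing `priority` (pass the negated distance transform to grow basins
// from distance maxima outward). Every mask voxel receives a label.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n);
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  long counter = 0;
  for (int i = 0; i < n; ++i) {
    lab[i] = markers[i];
    if (markers[i] > 0)
      pq.push(WsItem{priority[i], counter++, i, markers[i]});
  }
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    int i = it.idx;
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = it.label;
        pq.push(WsItem{priority[j], counter++, j, it.label});
      }
    }
  }
  return lab;
}

// Non-maximum suppression of a gradient-magnitude map along the local
// gradient direction (trilinear sampling at +/- 1 voxel step). The 3D
// stand-in for the thin-edge step of a Canny detector.
// [[Rcpp::export(name = ".cpp_nms")]]
NumericVector cpp_nms(NumericVector gm, NumericVector gz, NumericVector gy,
                      NumericVector gx, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  NumericVector out(n);
  auto sample = [&](double z, double y, double x) -> double {
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
        x1 = std::min(x0 + 1, nx - 1);
    double fz = z - z0, fy = y - y0, fx = x - x0;
    double c00 = gm[idx3(z0, y0, x0, nz, ny)] * (1 - fz) + gm[idx3(z1, y0, x0, nz, ny)] * fz;
    double c01 = gm[idx3(z0, y0, x1, nz, ny)] * (1 - fz) + gm[idx3(z1, y0, x1, nz, ny)] * fz;
    double c10 = gm[idx3(z0, y1, x0, nz, ny)] * (1 - fz) + gm[idx3(z1, y1, x0, nz, ny)] * fz;
    double c11 = gm[idx3(z0, y1, x1, nz, ny)] * (1 - fz) + gm[idx3(z1, y1, x1, nz, ny)] * fz;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fx) + c1 * fx;
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        double g = gm[i];
        if (g <= 0) { out[i] = 0; continue; }
        double dzv = gz[i] / g, dyv = gy[i] / g, dxv = gx[i] / g;
        double fwd = sample(z + dzv, y + dyv, x + dxv);
        double bwd = sample(z - dzv, y - dyv, x - dxv);
        out[i] = (g >= fwd && g >= bwd) ? g : 0.0;
      }
  return out;
}

// ---- iso-surface area by marching tetrahedra -------------------------------

struct P3 { double z, y, x; };

static inline P3 interp(const P3 &a, const P3 &b, double va, double vb,
                        double level) {
  double t = (level - va) / (vb - va);
  return P3{a.z + t * (b.z - a.z), a.y + t * (b.y - a.y), a.x + t * (b.x - a.x)};
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  double cz = uy * vx - ux * vy;
  double cy = ux * vz - uz * vx;
  double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

// Area of the level-`level` iso-surface of a scalar field, in the physical
// units implied by `spacing` (per-axis voxel size).
// [[Rcpp::export(name = ".cpp_isosurface_area")]]
double cpp_isosurface_area(NumericVector field, IntegerVector dims,
                           NumericVector spacing, double level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  // cube corner offsets (dz, dy, dx) indexed 0..7: bit0=dz, bit1=dy, bit2=dx
  const int cz[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cx[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // 6 tetrahedra sharing the 0-7 main diagonal
  const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                          {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  double area = 0.0;
  double val[8];
  P3 pos[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + cz[c], yy = y + cy[c], xx = x + cx[c];
          val[c] = field[idx3(zz, yy, xx, nz, ny)];
          pos[c] = P3{zz * sz, yy * sy, xx * sx};
          if (val[c] < level) any_lo = true; else any_hi = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int above[4], below[4], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[tv[c]] >= level) above[na++] = tv[c];
            else below[nb++] = tv[c];
          }
          if (na == 0 || nb == 0) continue;
          if (na == 1 || nb == 1) {
            int apex = (na == 1) ? above[0] : below[0];
            int *others = (na == 1) ? below : above;
            P3 p0 = interp(pos[apex], pos[others[0]], val[apex], val[others[0]], level);
            P3 p1 = interp(pos[apex], pos[others[1]], val[apex], val[others[1]], level);
            P3 p2 = interp(pos[apex], pos[others[2]], val[apex], val[others[2]], level);
            area += tri_area(p0, p1, p2);
          } else {  // 2-2: quad split into two triangles
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            P3 p0 = interp(pos[a0], pos[b0], val[a0], val[b0], level);
            P3 p1 = interp(pos[a0], pos[b1], val[a0], val[b1], level);
            P3 p2 = interp(pos[a1], pos[b1], val[a1], val[b1], level);
            P3 p3 = interp(pos[a1], pos[b0], val[a1], val[b0], level);
            area += tri_area(p0, p1, p2);
            area += tri_area(p0, p2, p3);
          }
        }
      }
  return area;
}
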