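// Low-level 3D image primitives for nuclear segmentation.
//
// All volumes are passed as flat vectors in R's column-major layout with
// dim = (nz, ny, nx): linear index = z + nz*y + nz*ny*x (0-based here).
// Connectivity is 6-neighbour (face adjacency) throughout; this keeps
// nuclei separated by a single background voxel distinct even diagonally.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// 6-connected component labelling of a boolean mask (BFS, labels 1..K in
// raster order of first encounter -> deterministic).
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  const int dz[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dx[6] = { 0, 0, 0, 0, 1, -1 };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cz = c % nz, cy = (c / nz) % ny, cx = c / (nz * ny);
          for (int k = 0; k < 6; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform with anisotropic spacing (um), by the
// Felzenszwalb-Huttenlocher separable lower-envelope algorithm on squared
// distances. Returns distance-to-background in um for voxels inside the mask.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double s, int n, std::vector<int>& v,
                 std::vector<double>& zbound) {
  // squared-distance transform of sampled function f with sample spacing s;
  // f must be finite (background squared distances capped at a large value)
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zbound[0] = -INF;
  zbound[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s;
    double inter;
    while (true) {
      double sv = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      if (k > 0 && inter <= zbound[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbound[k] = inter;
    zbound[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zbound[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  // cap: larger than any achievable squared distance in the domain
  const double ez = nz * spacing[0], ey = ny * spacing[1], ex = nx * spacing[2];
  const double BIG = 4.0 * (ez * ez + ey * ey + ex * ex) + 1.0;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, spacing[0], nz, v, zb);
      for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, spacing[1], ny, v, zb);
      for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
      dt1d(f, d, spacing[2], nx, v, zb);
      for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = d[x];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale morphological reconstruction by dilation (marker under mask),
// 6-connectivity; Vincent's hybrid algorithm (raster sweeps + FIFO queue).
// [[Rcpp::export(name = ".cpp_reconstruct")]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector maskimg,
                              IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  NumericVector J(n);
  for (int i = 0; i < n; ++i) J[i] = std::min(marker[i], maskimg[i]);

  // forward sweep: neighbours already visited in raster order (x,y,z asc)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        double m = J[i];
        if (z > 0) m = std::max(m, J[idx3(z - 1, y, x, nz, ny)]);
        if (y > 0) m = std::max(m, J[idx3(z, y - 1, x, nz, ny)]);
        if (x > 0) m = std::max(m, J[idx3(z, y, x - 1, nz, ny)]);
        J[i] = std::min(m, maskimg[i]);
      }
  // backward sweep + queue seeding
  std::queue<int> fifo;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        int i = idx3(z, y, x, nz, ny);
        double m = J[i];
        if (z < nz - 1) m = std::max(m, J[idx3(z + 1, y, x, nz, ny)]);
        if (y < ny - 1) m = std::max(m, J[idx3(z, y + 1, x, nz, ny)]);
        if (x < nx - 1) m = std::max(m, J[idx3(z, y, x + 1, nz, ny)]);
        J[i] = std::min(m, maskimg[i]);
        // queue if some later-scanned neighbour could still grow
        bool push = false;
        if (z < nz - 1) { int j = idx3(z + 1, y, x, nz, ny);
          if (J[j] < J[i] && J[j] < maskimg[j]) push = true; }
        if (!push && y < ny - 1) { int j = idx3(z, y + 1, x, nz, ny);
          if (J[j] < J[i] && J[j] < maskimg[j]) push = true; }
        if (!push && x < nx - 1) { int j = idx3(z, y, x + 1, nz, ny);
          if (J[j] < J[i] && J[j] < maskimg[j]) push = true; }
        if (push) fifo.push(i);
      }
  const int dz[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dx[6] = { 0, 0, 0, 0, 1, -1 };
  while (!fifo.empty()) {
    int i = fifo.front(); fifo.pop();
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (J[j] < J[i] && J[j] < maskimg[j]) {
        J[j] = std::min(J[i], maskimg[j]);
        fifo.push(j);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Seeded watershed on a priority image (lower values flooded first),
// restricted to mask. Seeds carry positive labels. Label-on-push flooding
// with FIFO tie-break (insertion counter) -> fully deterministic.
struct WsNode {
  double prio;
  long long order;
  int index;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.order > b.order;                        // FIFO on ties
  }
};

// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector prio, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  for (int i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({ prio[i], counter++, i });
    }
  const int dz[6] = { 1, -1, 0, 0, 0, 0 };
  const int dy[6] = { 0, 0, 1, -1, 0, 0 };
  const int dx[6] = { 0, 0, 0, 0, 1, -1 };
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int i = nd.index;
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[i];
        pq.push({ prio[j], counter++, j });
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, sigma per axis in voxel units, reflect boundary.
static void blur_axis(std::vector<double>& g, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) {
    kern[k + r] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += kern[k + r];
  }
  for (auto& w : kern) w /= s;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), out(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : a, y, x;
        if (axis == 0) { y = a; x = b; }
        else if (axis == 1) { z = a; y = t; x = b; }
        else { z = a; y = b; x = t; }
        line[t] = g[idx3(z, y, x, nz, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int u = t + k;
          if (u < 0) u = -u - 1;              // reflect
          if (u >= len) u = 2 * len - u - 1;
          if (u < 0) u = 0;                    // degenerate short axes
          if (u >= len) u = len - 1;
          acc += kern[k + r] * line[u];
        }
        out[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int z = axis == 0 ? t : a, y, x;
        if (axis == 0) { y = a; x = b; }
        else if (axis == 1) { z = a; y = t; x = b; }
        else { z = a; y = b; x = t; }
        g[idx3(z, y, x, nz, ny)] = out[t];
      }
    }
}

// [[Rcpp::export(name = ".cpp_blur3d")]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dim,
                         NumericVector sigma_voxels) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> g(vol.begin(), vol.end());
  blur_axis(g, nz, ny, nx, 0, sigma_voxels[0]);
  blur_axis(g, nz, ny, nx, 1, sigma_voxels[1]);
  blur_axis(g, nz, ny, nx, 2, sigma_voxels[2]);
  return NumericVector(g.begin(), g.end());
}
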