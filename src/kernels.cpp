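#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arrays are R 3D arrays in (z, y, x) order, i.e. dim = (nz, ny, nx) with z
// the fastest-varying index.  idx = z + nz*(y + ny*x).

static inline int at(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm applied per axis with physical sample spacing).
// Computes distance to the nearest "seed" voxel (seed = TRUE).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double w2,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seed, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // finite sentinel: Inf breaks the parabola-intersection arithmetic
  const double diag = nz * dz + ny * dy + nx * dx;
  const double INF = 4.0 * diag * diag + 1.0;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = seed[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[at(z, y, x, nz, ny)];
      dt1d(f, d, nz, dz * dz, v, zb);
      for (int z = 0; z < nz; ++z) out[at(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[at(z, y, x, nz, ny)];
      dt1d(f, d, ny, dy * dy, v, zb);
      for (int y = 0; y < ny; ++y) out[at(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[at(z, y, x, nz, ny)];
      dt1d(f, d, nx, dx * dx, v, zb);
      for (int x = 0; x < nx; ++x) out[at(z, y, x, nz, ny)] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, foreground connectivity 6 or 26.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        if (oz == 0 && oy == 0 && ox == 0) continue;
        int manh = std::abs(oz) + std::abs(oy) + std::abs(ox);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({oz, oy, ox});
      }
  int next = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = at(z0, y0, x0, nz, ny);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
          for (auto& o : offs) {
            int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = at(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// ICM sweeps for the HMRF posterior with Potts energy.  Labels are 1..K inside
// the mask, 0 outside; voxels outside the mask never contribute to the
// neighbour count.  Ties break toward the lower class index.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_icm(NumericVector intensity, LogicalVector mask, IntegerVector init,
             IntegerVector dim, NumericVector mu, double sigma, NumericVector logpi,
             double beta, int connectivity, int max_sweeps) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int K = mu.size();
  IntegerVector lab(clone(init));
  std::vector<std::array<int,3>> offs;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        if (oz == 0 && oy == 0 && ox == 0) continue;
        int manh = std::abs(oz) + std::abs(oy) + std::abs(ox);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({oz, oy, ox});
      }
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int sweeps = 0;
  bool changed = true;
  std::vector<int> nb(K);
  while (changed && sweeps < max_sweeps) {
    changed = false;
    ++sweeps;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int i = at(z, y, x, nz, ny);
          if (!mask[i]) continue;
          std::fill(nb.begin(), nb.end(), 0);
          int nnb = 0;
          for (auto& o : offs) {
            int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = at(zz, yy, xx, nz, ny);
            if (mask[j]) { ++nb[lab[j] - 1]; ++nnb; }
          }
          int best = 0;
          double bestv = -std::numeric_limits<double>::infinity();
          for (int c = 0; c < K; ++c) {
            double r = intensity[i] - mu[c];
            // Potts energy beta * (# differently-labelled neighbours)
            double val = logpi[c] - r * r * inv2s2 - beta * (nnb - nb[c]);
            if (val > bestv) { bestv = val; best = c; }
          }
          if (lab[i] != best + 1) { lab[i] = best + 1; changed = true; }
        }
  }
  return List::create(_["labels"] = lab, _["sweeps"] = sweeps,
                      _["converged"] = !changed);
}

// ---------------------------------------------------------------------------
// Regional maxima (26-connected plateaus) of a masked image with peak >= offset.
// A plateau is a maximal 26-connected set of equal-valued masked voxels; it is
// a regional maximum iff no member has a strictly greater masked neighbour.
// Returns an integer label image (0 = not a maximum).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector img, LogicalVector mask,
                                  IntegerVector dim, double offset) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<char> visited(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox)
        if (oz || oy || ox) offs.push_back({oz, oy, ox});
  int next = 0;
  std::vector<int> comp, stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = at(z0, y0, x0, nz, ny);
        if (!mask[i0] || visited[i0] || img[i0] < offset) continue;
        double v = img[i0];
        bool is_max = true;
        comp.clear(); stack.clear();
        visited[i0] = 1;
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          comp.push_back(i);
          int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
          for (auto& o : offs) {
            int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = at(zz, yy, xx, nz, ny);
            if (!mask[j]) continue;
            if (img[j] > v) { is_max = false; continue; }
            if (img[j] == v && !visited[j]) { visited[j] = 1; stack.push_back(j); }
          }
        }
        if (is_max) {
          ++next;
          for (int i : comp) lab[i] = next;
        }
      }
  return lab;
}
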