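#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at fractional 0-based voxel
// indices. Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix idx, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int i = 0; i < n; ++i) {
    const double x = idx(i, 0), y = idx(i, 1), z = idx(i, 2);
    if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
          x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t b = x0 * sx + y0 * sy + z0 * sz;
    const int dx = (nx > 1), dy = (ny > 1), dz = (nz > 1);
    const double c000 = v[b];
    const double c100 = v[b + dx * sx];
    const double c010 = v[b + dy * sy];
    const double c110 = v[b + dx * sx + dy * sy];
    const double c001 = v[b + dz * sz];
    const double c101 = v[b + dx * sx + dz * sz];
    const double c011 = v[b + dy * sy + dz * sz];
    const double c111 = v[b + dx * sx + dy * sy + dz * sz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour interpolation (for label masks).
// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector vol, IntegerVector dims,
                          NumericMatrix idx, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i) {
    const long xi = std::lround(idx(i, 0));
    const long yi = std::lround(idx(i, 1));
    const long zi = std::lround(idx(i, 2));
    if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
      out[i] = fill;
    } else {
      out[i] = v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
    }
  }
  return out;
}

// Joint histogram with partial-volume (bilinear Parzen) weighting.
// fbin/mbin are continuous bin coordinates in [0, nbins - 1]; each sample
// spreads linearly over the two adjacent bins in each image, i.e. over
// four joint cells. Returns an nbins x nbins count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist_pv(NumericVector fbin, NumericVector mbin,
                                int nbins) {
  const int n = fbin.size();
  NumericMatrix H(nbins, nbins);
  for (int i = 0; i < n; ++i) {
    double f = fbin[i], m = mbin[i];
    if (ISNAN(f) || ISNAN(m)) continue;
    if (f < 0) f = 0; else if (f > nbins - 1) f = nbins - 1;
    if (m < 0) m = 0; else if (m > nbins - 1) m = nbins - 1;
    int f0 = (int)std::floor(f), m0 = (int)std::floor(m);
    if (f0 == nbins - 1) --f0;
    if (m0 == nbins - 1) --m0;
    if (f0 < 0) f0 = 0;
    if (m0 < 0) m0 = 0;
    const double wf = f - f0, wm = m - m0;
    H(f0, m0)         += (1 - wf) * (1 - wm);
    H(f0 + 1, m0)     += wf * (1 - wm);
    H(f0, m0 + 1)     += (1 - wf) * wm;
    H(f0 + 1, m0 + 1) += wf * wm;
  }
  return H;
}

// For every row of `a`, the distance to the nearest row of `b` (brute
// force, used for surface-distance metrics; coordinates in mm).
// [[Rcpp::export]]
NumericVector cpp_nearest_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - b(j, 0), dy = yi - b(j, 1), dz = zi - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Face-connected boundary voxels of a binary mask: voxels that are 1 and
// have at least one 6-neighbour that is 0 or lies outside the grid.
// Returns their 0-based integer indices as an n x 3 matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_voxels(NumericVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = mask.begin();
  std::vector<int> xs, ys, zs;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t o = x + y * sy + z * sz;
        if (v[o] == 0) continue;
        bool boundary =
          (x == 0 || v[o - 1] == 0) || (x == nx - 1 || v[o + 1] == 0) ||
          (y == 0 || v[o - sy] == 0) || (y == ny - 1 || v[o + sy] == 0) ||
          (z == 0 || v[o - sz] == 0) || (z == nz - 1 || v[o + sz] == 0);
        if (boundary) {
          xs.push_back(x); ys.push_back(y); zs.push_back(z);
        }
      }
    }
  }
  const int n = xs.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}
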