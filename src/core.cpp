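#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Voxel centers sit at (i + 0.5) * voxel in each dimension (0-based i).
// All coordinates below are in voxel units unless noted.

static inline int wrap_index(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Mark voxels whose center lies within `radius` of the segment p0--p1.
// With wrap = true indices are wrapped periodically (cylinder chords through
// a periodic box); otherwise out-of-box voxels are skipped. Optionally write
// `label` into `labels` for newly marked voxels. Returns number of voxels
// newly set.
// [[Rcpp::export]]
int cpp_mark_tube(IntegerVector occ, IntegerVector dims,
                  NumericVector p0, NumericVector p1, double radius,
                  bool wrap, IntegerVector labels, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ax = p1[0] - p0[0], ay = p1[1] - p0[1], az = p1[2] - p0[2];
  const double len2 = ax * ax + ay * ay + az * az;
  const double len = std::sqrt(len2);
  const bool use_labels = labels.size() == occ.size();
  int newly = 0;

  const double step = std::max(0.5, radius / 2.5);
  const int halo = (int)std::ceil(radius + step / 2 + 1.0);
  const double r2 = radius * radius;
  const int nsamp = std::max(1, (int)std::ceil(len / step) + 1);

  // de-duplicate per-voxel work with a coarse visited stamp on the sample axis
  for (int s = 0; s <= nsamp; ++s) {
    double t = len * (double)s / (double)nsamp;
    double cx = p0[0] + (len > 0 ? ax * t / len : 0.0);
    double cy = p0[1] + (len > 0 ? ay * t / len : 0.0);
    double cz = p0[2] + (len > 0 ? az * t / len : 0.0);
    int ix0 = (int)std::floor(cx - 0.5), iy0 = (int)std::floor(cy - 0.5),
        iz0 = (int)std::floor(cz - 0.5);
    for (int dz = -halo; dz <= halo; ++dz)
      for (int dy = -halo; dy <= halo; ++dy)
        for (int dx = -halo; dx <= halo; ++dx) {
          int ix = ix0 + dx, iy = iy0 + dy, iz = iz0 + dz;
          double vx = ix + 0.5, vy = iy + 0.5, vz = iz + 0.5;
          // squared distance from voxel center to segment
          double d2;
          if (len2 == 0.0) {
            double ex = vx - p0[0], ey = vy - p0[1], ez = vz - p0[2];
            d2 = ex * ex + ey * ey + ez * ez;
          } else {
            double ex = vx - p0[0], ey = vy - p0[1], ez = vz - p0[2];
            double tt = (ex * ax + ey * ay + ez * az) / len2;
            if (tt < 0.0) tt = 0.0;
            if (tt > 1.0) tt = 1.0;
            double qx = ex - tt * ax, qy = ey - tt * ay, qz = ez - tt * az;
            d2 = qx * qx + qy * qy + qz * qz;
          }
          if (d2 > r2) continue;
          int jx, jy, jz;
          if (wrap) {
            jx = wrap_index(ix, nx); jy = wrap_index(iy, ny); jz = wrap_index(iz, nz);
          } else {
            if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
              continue;
            jx = ix; jy = iy; jz = iz;
          }
          R_xlen_t idx = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
          if (!occ[idx]) {
            occ[idx] = 1;
            ++newly;
          }
          if (use_labels && labels[idx] == 0) labels[idx] = label;
        }
  }
  return newly;
}

// Random-walk phase accumulation over a frequency-shift grid.
// omega: rad/s on the grid; occ: 1 = intravascular (excluded, impermeable);
// voxel: um; step_len: um; dt: s. refocus_step > 0 flips the phase-accrual
// sign from that step on (spin echo at TE/2). Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_walk(NumericVector omega, IntegerVector occ,
                       IntegerVector dims, double voxel,
                       int n_walkers, int n_steps, double dt,
                       double step_len, int refocus_step,
                       bool lattice_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * voxel, Ly = ny * voxel, Lz = nz * voxel;
  std::vector<double> px(n_walkers), py(n_walkers), pz(n_walkers),
      phi(n_walkers, 0.0);

  for (int w = 0; w < n_walkers; ++w) {
    int tries = 0;
    for (;;) {
      double x = unif_rand() * Lx, y = unif_rand() * Ly, z = unif_rand() * Lz;
      int ix = (int)(x / voxel), iy = (int)(y / voxel), iz = (int)(z / voxel);
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      if (!occ[idx]) { px[w] = x; py[w] = y; pz[w] = z; break; }
      if (++tries > 100000)
        stop("could not place walker in extravascular space");
    }
  }

  for (int k = 0; k < n_steps; ++k) {
    double sign = (refocus_step > 0 && k >= refocus_step) ? -1.0 : 1.0;
    for (int w = 0; w < n_walkers; ++w) {
      int ix = (int)(px[w] / voxel), iy = (int)(py[w] / voxel),
          iz = (int)(pz[w] / voxel);
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      phi[w] += sign * omega[idx] * dt;
      if (step_len > 0.0) {
        double ux, uy, uz;
        if (lattice_steps) {
          double u = unif_rand() * 6.0;
          int face = (int)u;
          if (face > 5) face = 5;
          ux = uy = uz = 0.0;
          double s = (face % 2 == 0) ? 1.0 : -1.0;
          if (face < 2) ux = s; else if (face < 4) uy = s; else uz = s;
        } else {
          double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
          double nrm = std::sqrt(gx * gx + gy * gy + gz * gz);
          if (nrm == 0.0) continue;
          ux = gx / nrm; uy = gy / nrm; uz = gz / nrm;
        }
        double x = px[w] + step_len * ux;
        double y = py[w] + step_len * uy;
        double z = pz[w] + step_len * uz;
        x -= Lx * std::floor(x / Lx);
        y -= Ly * std::floor(y / Ly);
        z -= Lz * std::floor(z / Lz);
        int jx = (int)(x / voxel), jy = (int)(y / voxel), jz = (int)(z / voxel);
        if (jx >= nx) jx = nx - 1;
        if (jy >= ny) jy = ny - 1;
        if (jz >= nz) jz = nz - 1;
        R_xlen_t jdx = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
        if (!occ[jdx]) { px[w] = x; py[w] = y; pz[w] = z; }
        // else: rejected step, walker stays in place (impermeable wall)
      }
    }
  }

  double sre = 0.0, sim = 0.0;
  for (int w = 0; w < n_walkers; ++w) {
    sre += std::cos(phi[w]);
    sim += std::sin(phi[w]);
  }
  NumericVector out(2);
  out[0] = sre / n_walkers;
  out[1] = sim / n_walkers;
  return out;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)

static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    if (s <= z[k]) { v[k] = q; } else { ++k; v[k] = q; z[k] = s; }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from each voxel to the nearest
// zero voxel of mask. Voxels where mask == 0 get 0. Foreground values are
// capped by a large sentinel when no background exists.
// [[Rcpp::export]]
NumericVector cpp_sq_edt(IntegerVector mask, IntegerVector dims) {
  const double BIG = 1e12;  // > any achievable squared grid distance
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ++ix) f[ix] = d[base + ix];
      edt_1d(f, dd, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) d[base + ix] = std::min(dd[ix], BIG);
    }
  // pass along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)nx * ny * (R_xlen_t)iz;
      for (int iy = 0; iy < ny; ++iy) f[iy] = d[base + (R_xlen_t)nx * iy];
      edt_1d(f, dd, v, z, ny);
      for (int iy = 0; iy < ny; ++iy)
        d[base + (R_xlen_t)nx * iy] = std::min(dd[iy], BIG);
    }
  // pass along z
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)nx * iy;
      for (int iz = 0; iz < nz; ++iz) f[iz] = d[base + (R_xlen_t)nx * ny * iz];
      edt_1d(f, dd, v, z, nz);
      for (int iz = 0; iz < nz; ++iz)
        d[base + (R_xlen_t)nx * ny * iz] = std::min(dd[iz], BIG);
    }
  return d;
}

// Local thickness by sphere painting: for every foreground voxel c with
// inscribed radius rho[c] (voxel units), every mask voxel q with
// ||q - c||^2 <= rho[c]^2 receives thickness >= 2 * rho[c].
// [[Rcpp::export]]
NumericVector cpp_paint_thickness(IntegerVector mask, IntegerVector dims,
                                  NumericVector rho) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t c = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        if (!mask[c] || rho[c] <= 0) continue;
        double r = rho[c], r2 = r * r;
        int h = (int)std::floor(r);
        for (int dz = -h; dz <= h; ++dz)
          for (int dy = -h; dy <= h; ++dy)
            for (int dx = -h; dx <= h; ++dx) {
              int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
                continue;
              double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
              if (d2 > r2) continue;
              R_xlen_t q = (R_xlen_t)jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
              if (mask[q] && th[q] < 2.0 * r) th[q] = 2.0 * r;
            }
      }
  return th;
}
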