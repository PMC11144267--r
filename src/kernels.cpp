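// Hot numerical kernels: MHP summation, 3DDDA voxel ray tracing against
// van der Waals spheres, and probe-expanded sphere sampling used for both
// Shrake-Rupley areas and Connolly-style surface point clouds.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// ---------------------------------------------------------------------------
// MHP: per-point, per-subunit sums of f_i * exp(-r_ij / decay), hard cutoff
// at r_ij < rcut (contribution identically zero at and beyond the cutoff).
// subunit is 1-based; nsub columns in the result.
// [[Rcpp::export]]
NumericMatrix cpp_mhp_contrib(NumericMatrix pts, NumericMatrix axyz,
                              NumericVector f, IntegerVector subunit,
                              int nsub, double rcut, double decay) {
  const int np = pts.nrow(), na = axyz.nrow();
  NumericMatrix out(np, nsub);
  const double rcut2 = rcut * rcut;
  for (int j = 0; j < np; ++j) {
    const double px = pts(j, 0), py = pts(j, 1), pz = pts(j, 2);
    for (int i = 0; i < na; ++i) {
      const double d2 = sq(px - axyz(i, 0)) + sq(py - axyz(i, 1)) +
                        sq(pz - axyz(i, 2));
      if (d2 < rcut2) {
        out(j, subunit[i] - 1) += f[i] * std::exp(-std::sqrt(d2) / decay);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uniform voxel grid over the atom set; each voxel lists every atom whose
// sphere's bounding box overlaps it.
struct VoxelGrid {
  double x0, y0, z0, h;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  int idx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
};

static VoxelGrid build_grid(const NumericMatrix& axyz,
                            const NumericVector& radii, double h) {
  VoxelGrid g;
  const int na = axyz.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = std::numeric_limits<double>::infinity();
    hi[k] = -std::numeric_limits<double>::infinity();
  }
  double rmax = 0.0;
  for (int i = 0; i < na; ++i) {
    rmax = std::max(rmax, (double)radii[i]);
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], axyz(i, k));
      hi[k] = std::max(hi[k], axyz(i, k));
    }
  }
  const double pad = rmax + 1e-6;
  g.x0 = lo[0] - pad; g.y0 = lo[1] - pad; g.z0 = lo[2] - pad;
  g.h = h;
  g.nx = std::max(1, (int)std::ceil((hi[0] + pad - g.x0) / h));
  g.ny = std::max(1, (int)std::ceil((hi[1] + pad - g.y0) / h));
  g.nz = std::max(1, (int)std::ceil((hi[2] + pad - g.z0) / h));
  g.cells.resize((size_t)g.nx * g.ny * g.nz);
  for (int i = 0; i < na; ++i) {
    const double r = radii[i];
    int i0 = std::max(0, (int)std::floor((axyz(i, 0) - r - g.x0) / h));
    int i1 = std::min(g.nx - 1, (int)std::floor((axyz(i, 0) + r - g.x0) / h));
    int j0 = std::max(0, (int)std::floor((axyz(i, 1) - r - g.y0) / h));
    int j1 = std::min(g.ny - 1, (int)std::floor((axyz(i, 1) + r - g.y0) / h));
    int k0 = std::max(0, (int)std::floor((axyz(i, 2) - r - g.z0) / h));
    int k1 = std::min(g.nz - 1, (int)std::floor((axyz(i, 2) + r - g.z0) / h));
    for (int kz = k0; kz <= k1; ++kz)
      for (int ky = j0; ky <= j1; ++ky)
        for (int kx = i0; kx <= i1; ++kx)
          g.cells[g.idx(kx, ky, kz)].push_back(i);
  }
  return g;
}

// Smallest non-negative t with |o + t d - c| = r; tangent rays count as hits.
static inline double ray_sphere_t(const double* o, const double* d,
                                  const double* c, double r) {
  const double ox = o[0] - c[0], oy = o[1] - c[1], oz = o[2] - c[2];
  const double b = ox * d[0] + oy * d[1] + oz * d[2];
  const double cc = ox * ox + oy * oy + oz * oz - r * r;
  double disc = b * b - cc;
  if (disc < 0.0) return -1.0;
  disc = std::sqrt(disc);
  double t = -b - disc;
  if (t < 0.0) t = -b + disc;
  return (t >= 0.0) ? t : -1.0;
}

// 3DDDA traversal: voxels visited in order of increasing distance along the
// ray; the walk stops as soon as the entry distance of the current voxel
// exceeds the best hit found (or tmax).
// [[Rcpp::export]]
List cpp_trace_rays(NumericMatrix orig, NumericMatrix dir,
                    NumericMatrix axyz, NumericVector radii,
                    double voxel, double tmax) {
  const int nr = orig.nrow(), na = axyz.nrow();
  IntegerVector hit(nr);
  NumericVector tdist(nr, NA_REAL);
  if (na == 0) return List::create(_["atom"] = hit, _["t"] = tdist);
  VoxelGrid g = build_grid(axyz, radii, voxel);
  std::vector<int> stamp(na, -1);
  for (int q = 0; q < nr; ++q) {
    double o[3] = { orig(q, 0), orig(q, 1), orig(q, 2) };
    double d[3] = { dir(q, 0), dir(q, 1), dir(q, 2) };
    const double dn = std::sqrt(sq(d[0]) + sq(d[1]) + sq(d[2]));
    for (int k = 0; k < 3; ++k) d[k] /= dn;
    // clip the ray to the grid box
    double t0 = 0.0, t1 = tmax;
    const double glo[3] = { g.x0, g.y0, g.z0 };
    const double ghi[3] = { g.x0 + g.nx * g.h, g.y0 + g.ny * g.h,
                            g.z0 + g.nz * g.h };
    bool outside = false;
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(d[k]) < 1e-300) {
        if (o[k] < glo[k] || o[k] > ghi[k]) { outside = true; break; }
      } else {
        double ta = (glo[k] - o[k]) / d[k], tb = (ghi[k] - o[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      }
    }
    if (outside || t0 > t1) continue;
    double px = o[0] + (t0 + 1e-9) * d[0];
    double py = o[1] + (t0 + 1e-9) * d[1];
    double pz = o[2] + (t0 + 1e-9) * d[2];
    int ix = std::min(g.nx - 1, std::max(0, (int)std::floor((px - g.x0) / g.h)));
    int iy = std::min(g.ny - 1, std::max(0, (int)std::floor((py - g.y0) / g.h)));
    int iz = std::min(g.nz - 1, std::max(0, (int)std::floor((pz - g.z0) / g.h)));
    const int sx = d[0] > 0 ? 1 : -1, sy = d[1] > 0 ? 1 : -1,
              sz = d[2] > 0 ? 1 : -1;
    const double inf = std::numeric_limits<double>::infinity();
    double tmx = inf, tmy = inf, tmz = inf, tdx = inf, tdy = inf, tdz = inf;
    if (std::fabs(d[0]) > 1e-300) {
      tmx = ((g.x0 + (ix + (sx > 0 ? 1 : 0)) * g.h) - o[0]) / d[0];
      tdx = g.h / std::fabs(d[0]);
    }
    if (std::fabs(d[1]) > 1e-300) {
      tmy = ((g.y0 + (iy + (sy > 0 ? 1 : 0)) * g.h) - o[1]) / d[1];
      tdy = g.h / std::fabs(d[1]);
    }
    if (std::fabs(d[2]) > 1e-300) {
      tmz = ((g.z0 + (iz + (sz > 0 ? 1 : 0)) * g.h) - o[2]) / d[2];
      tdz = g.h / std::fabs(d[2]);
    }
    double best_t = inf;
    int best_atom = -1;
    double t_entry = t0;
    while (true) {
      if (t_entry > std::min(best_t, t1)) break;
      const std::vector<int>& cell = g.cells[g.idx(ix, iy, iz)];
      for (size_t m = 0; m < cell.size(); ++m) {
        const int i = cell[m];
        if (stamp[i] == q) continue;
        stamp[i] = q;
        double c[3] = { axyz(i, 0), axyz(i, 1), axyz(i, 2) };
        const double t = ray_sphere_t(o, d, c, radii[i]);
        if (t >= 0.0 && t < best_t) { best_t = t; best_atom = i; }
      }
      // advance to the next voxel along the ray
      if (tmx <= tmy && tmx <= tmz) {
        t_entry = tmx; ix += sx; tmx += tdx;
        if (ix < 0 || ix >= g.nx) break;
      } else if (tmy <= tmz) {
        t_entry = tmy; iy += sy; tmy += tdy;
        if (iy < 0 || iy >= g.ny) break;
      } else {
        t_entry = tmz; iz += sz; tmz += tdz;
        if (iz < 0 || iz >= g.nz) break;
      }
    }
    if (best_atom >= 0 && best_t <= tmax) {
      hit[q] = best_atom + 1;
      tdist[q] = best_t;
    }
  }
  return List::create(_["atom"] = hit, _["t"] = tdist);
}

// ---------------------------------------------------------------------------
// Deterministic Fibonacci-lattice directions on the unit sphere.
// [[Rcpp::export]]
NumericMatrix cpp_fibonacci_sphere(int n) {
  NumericMatrix u(n, 3);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    const double z = 1.0 - 2.0 * (i + 0.5) / n;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = ga * i;
    u(i, 0) = r * std::cos(th);
    u(i, 1) = r * std::sin(th);
    u(i, 2) = z;
  }
  return u;
}

// Sample each atom's probe-expanded sphere (radius r_i + probe) on a shared
// Fibonacci lattice. A sample is exposed when it is not strictly inside any
// other atom's expanded sphere; buried samples record the deepest blocker.
// Returns per-sample exposure flags and blocker indices (row-major:
// atom-major blocks of npts samples, 1-based blockers, 0 = exposed).
// [[Rcpp::export]]
List cpp_sphere_samples(NumericMatrix axyz, NumericVector radii,
                        double probe, int npts) {
  const int na = axyz.nrow();
  NumericMatrix u = cpp_fibonacci_sphere(npts);
  LogicalVector exposed((size_t)na * npts, true);
  IntegerVector blocker((size_t)na * npts, 0);
  if (na == 0)
    return List::create(_["dirs"] = u, _["exposed"] = exposed,
                        _["blocker"] = blocker);
  double rmax = 0.0;
  for (int i = 0; i < na; ++i) rmax = std::max(rmax, (double)radii[i]);
  VoxelGrid g = build_grid(axyz, radii, 2.0 * (rmax + probe) + 1e-6);
  // neighbour search via grid cells (cell size covers max interaction range)
  for (int i = 0; i < na; ++i) {
    const double ri = radii[i] + probe;
    std::vector<int> nbr;
    int cx = (int)std::floor((axyz(i, 0) - g.x0) / g.h);
    int cy = (int)std::floor((axyz(i, 1) - g.y0) / g.h);
    int cz = (int)std::floor((axyz(i, 2) - g.z0) / g.h);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int jx = cx + dx, jy = cy + dy, jz = cz + dz;
          if (jx < 0 || jx >= g.nx || jy < 0 || jy >= g.ny ||
              jz < 0 || jz >= g.nz) continue;
          const std::vector<int>& cell = g.cells[g.idx(jx, jy, jz)];
          for (size_t m = 0; m < cell.size(); ++m) {
            const int j = cell[m];
            if (j == i) continue;
            const double d2 = sq(axyz(i,0)-axyz(j,0)) + sq(axyz(i,1)-axyz(j,1))
                            + sq(axyz(i,2)-axyz(j,2));
            const double rr = ri + radii[j] + probe;
            if (d2 < rr * rr) nbr.push_back(j);
          }
        }
    for (int s = 0; s < npts; ++s) {
      const double px = axyz(i, 0) + ri * u(s, 0);
      const double py = axyz(i, 1) + ri * u(s, 1);
      const double pz = axyz(i, 2) + ri * u(s, 2);
      double deepest = 1e-9;  // strict containment tolerance
      int who = 0;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double dj = std::sqrt(sq(px - axyz(j, 0)) + sq(py - axyz(j, 1)) +
                                    sq(pz - axyz(j, 2)));
        const double pen = (radii[j] + probe) - dj;
        if (pen > deepest) { deepest = pen; who = j + 1; }
      }
      if (who > 0) {
        exposed[(size_t)i * npts + s] = false;
        blocker[(size_t)i * npts + s] = who;
      }
    }
  }
  return List::create(_["dirs"] = u, _["exposed"] = exposed,
                      _["blocker"] = blocker);
}

// For each row of A, is any row of B within cutoff?
// [[Rcpp::export]]
LogicalVector cpp_any_within(NumericMatrix A, NumericMatrix B, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  LogicalVector out(na, false);
  if (nb == 0) return out;
  NumericVector zero(nb, 0.0);
  // reuse the voxel grid as a point cell list (radius 0 spheres)
  VoxelGrid g = build_grid(B, zero, std::max(cutoff, 1e-3));
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < na; ++i) {
    // clamp the query into the grid box for cell lookup only; with cell
    // size >= cutoff the true neighbours still fall in the 27-cell stencil
    int cx = std::min(g.nx - 1, std::max(0, (int)std::floor((A(i, 0) - g.x0) / g.h)));
    int cy = std::min(g.ny - 1, std::max(0, (int)std::floor((A(i, 1) - g.y0) / g.h)));
    int cz = std::min(g.nz - 1, std::max(0, (int)std::floor((A(i, 2) - g.z0) / g.h)));
    if (A(i,0) < g.x0 - cutoff || A(i,0) > g.x0 + g.nx * g.h + cutoff ||
        A(i,1) < g.y0 - cutoff || A(i,1) > g.y0 + g.ny * g.h + cutoff ||
        A(i,2) < g.z0 - cutoff || A(i,2) > g.z0 + g.nz * g.h + cutoff)
      continue;
    bool found = false;
    for (int dz = -1; dz <= 1 && !found; ++dz)
      for (int dy = -1; dy <= 1 && !found; ++dy)
        for (int dx = -1; dx <= 1 && !found; ++dx) {
          const int jx = cx + dx, jy = cy + dy, jz = cz + dz;
          if (jx < 0 || jx >= g.nx || jy < 0 || jy >= g.ny ||
              jz < 0 || jz >= g.nz) continue;
          const std::vector<int>& cell = g.cells[g.idx(jx, jy, jz)];
          for (size_t m = 0; m < cell.size(); ++m) {
            const int j = cell[m];
            const double d2 = sq(A(i,0)-B(j,0)) + sq(A(i,1)-B(j,1)) +
                              sq(A(i,2)-B(j,2));
            if (d2 <= c2) { found = true; break; }
          }
        }
    out[i] = found;
  }
  return out;
}
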