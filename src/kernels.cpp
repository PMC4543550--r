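#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
#ifndef M_PI_2
#define M_PI_2 1.57079632679489661923
#endif
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rigid test-tube geometry: hemisphere of radius R centred at (0,0,R) capped
// by a cylinder x^2+y^2=R^2 for z in [R, H]; base pole at the origin.
// All queries are total functions of the point position.
// ---------------------------------------------------------------------------

struct SurfHit {
  double dist;          // unsigned distance to nearest wall point
  double nx, ny, nz;    // inward normal (wall -> lumen), zero-safe
  double fx, fy, fz;    // foot: nearest wall point
};

static inline SurfHit surf_query(double x, double y, double z,
                                 double R, double H) {
  SurfHit h;
  if (z > R) {
    double rho = std::sqrt(x * x + y * y);
    if (rho < 1e-12) {           // on the axis: direction degenerate, pick +x
      h.dist = R;
      h.nx = -1.0; h.ny = 0.0; h.nz = 0.0;
      h.fx = R; h.fy = 0.0; h.fz = z;
    } else {
      h.dist = std::fabs(R - rho);
      h.nx = -x / rho; h.ny = -y / rho; h.nz = 0.0;
      h.fx = x * R / rho; h.fy = y * R / rho; h.fz = z;
    }
  } else {
    double dx = x, dy = y, dz = z - R;           // from hemisphere centre
    double rad = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (rad < 1e-12) {           // at the centre: any direction; use down
      h.dist = R;
      h.nx = 0.0; h.ny = 0.0; h.nz = 1.0;
      h.fx = 0.0; h.fy = 0.0; h.fz = 0.0;
    } else {
      h.dist = std::fabs(R - rad);
      h.nx = -dx / rad; h.ny = -dy / rad; h.nz = -dz / rad;
      h.fx = dx * R / rad; h.fy = dy * R / rad; h.fz = R + dz * R / rad;
    }
  }
  return h;
}

// meridian arc length from the base pole to the wall projection of p
static inline double wall_arc(double x, double y, double z,
                              double R, double H) {
  if (z > R) return M_PI_2 * R + (z - R);
  double dx = x, dy = y, dz = z - R;
  double rad = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (rad < 1e-12) return M_PI_2 * R;   // centre projects to the junction ring
  double phi = std::acos(std::max(-1.0, std::min(1.0, -dz / rad)));
  return R * phi;
}

// unit tangent along the wall pointing toward decreasing arc; zero at pole
static inline void downhill(double x, double y, double z, double R, double H,
                            double &tx, double &ty, double &tz) {
  if (z > R) {
    tx = 0.0; ty = 0.0; tz = -1.0;
    return;
  }
  double dx = x, dy = y, dz = z - R;
  double rad = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (rad < 1e-12) { tx = ty = tz = 0.0; return; }
  double ux = dx / rad, uy = dy / rad, uz = dz / rad;
  double s = std::sqrt(ux * ux + uy * uy);      // sin(phi)
  if (s < 1e-12) { tx = ty = tz = 0.0; return; } // at/below the pole
  double cphi = -uz;                             // cos(phi), phi from -z axis
  // d(position)/d(phi) = (cphi*cth, cphi*sth, sin phi); downhill = -d/dphi
  tx = -cphi * ux / s;
  ty = -cphi * uy / s;
  tz = -s;
}

// [[Rcpp::export]]
List cpp_surface_query(NumericMatrix p, double R, double H) {
  int n = p.nrow();
  NumericVector d(n);
  NumericMatrix nor(n, 3), foot(n, 3);
  for (int i = 0; i < n; ++i) {
    SurfHit h = surf_query(p(i, 0), p(i, 1), p(i, 2), R, H);
    d[i] = h.dist;
    nor(i, 0) = h.nx; nor(i, 1) = h.ny; nor(i, 2) = h.nz;
    foot(i, 0) = h.fx; foot(i, 1) = h.fy; foot(i, 2) = h.fz;
  }
  return List::create(_["distance"] = d, _["normal"] = nor, _["foot"] = foot);
}

// [[Rcpp::export]]
NumericVector cpp_wall_height(NumericMatrix p, double R, double H) {
  int n = p.nrow();
  NumericVector a(n);
  for (int i = 0; i < n; ++i)
    a[i] = wall_arc(p(i, 0), p(i, 1), p(i, 2), R, H);
  return a;
}

// [[Rcpp::export]]
NumericMatrix cpp_downhill_tangent(NumericMatrix p, double R, double H) {
  int n = p.nrow();
  NumericMatrix t(n, 3);
  for (int i = 0; i < n; ++i) {
    double tx, ty, tz;
    downhill(p(i, 0), p(i, 1), p(i, 2), R, H, tx, ty, tz);
    t(i, 0) = tx; t(i, 1) = ty; t(i, 2) = tz;
  }
  return t;
}

// ---------------------------------------------------------------------------
// Forces. Intra-cell harmonic springs (all pairs, no cutoff), inter-cell
// Lennard-Jones with hard cutoff and capped short-range repulsion, linear
// wall adhesion within a cutoff. Velocities are in um/h.
// ---------------------------------------------------------------------------

static inline double lj_force_mag(double r, double eps, double sigma) {
  double q = sigma / r;
  double q6 = q * q * q * q * q * q;
  return (eps / r) * (12.0 * q6 * q6 - 6.0 * q6); // >0 repulsive
}

struct PairList {
  std::vector<int> a, b;
};

// spatial counting-sort order (bins of size bs): elements of the same and
// nearby bins become contiguous, which keeps the pair-force loop cache-local
static void spatial_order(const std::vector<double> &P, double bs,
                          std::vector<int> &order) {
  int n = (int)P.size() / 3;
  order.resize(n);
  if (n == 0) return;
  double minx = P[0], miny = P[1], minz = P[2];
  double maxx = P[0], maxy = P[1], maxz = P[2];
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, P[3*i]);   maxx = std::max(maxx, P[3*i]);
    miny = std::min(miny, P[3*i+1]); maxy = std::max(maxy, P[3*i+1]);
    minz = std::min(minz, P[3*i+2]); maxz = std::max(maxz, P[3*i+2]);
  }
  int nbx = std::max(1, (int)std::floor((maxx - minx) / bs) + 1);
  int nby = std::max(1, (int)std::floor((maxy - miny) / bs) + 1);
  int nbz = std::max(1, (int)std::floor((maxz - minz) / bs) + 1);
  size_t nbins = (size_t)nbx * nby * nbz;
  std::vector<int> binof(n);
  std::vector<int> start(nbins + 1, 0);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(nbx - 1, (int)std::floor((P[3*i] - minx) / bs));
    int iy = std::min(nby - 1, (int)std::floor((P[3*i+1] - miny) / bs));
    int iz = std::min(nbz - 1, (int)std::floor((P[3*i+2] - minz) / bs));
    binof[i] = ix + nbx * (iy + nby * iz);
    ++start[binof[i] + 1];
  }
  for (size_t b = 0; b < nbins; ++b) start[b + 1] += start[b];
  for (int i = 0; i < n; ++i) order[start[binof[i]]++] = i;
}

// spatial-hash pair search: all element pairs of *different* cells closer
// than `cutoff`, each pair once. Bins of cutoff/2 with a half stencil keep
// the candidate volume small.
static void find_pairs(const std::vector<double> &P,
                       const std::vector<int> &cell, double cutoff,
                       PairList &out) {
  int n = (int)P.size() / 3;
  out.a.clear(); out.b.clear();
  if (n == 0) return;
  double minx = P[0], miny = P[1], minz = P[2];
  double maxx = P[0], maxy = P[1], maxz = P[2];
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, P[3*i]);   maxx = std::max(maxx, P[3*i]);
    miny = std::min(miny, P[3*i+1]); maxy = std::max(maxy, P[3*i+1]);
    minz = std::min(minz, P[3*i+2]); maxz = std::max(maxz, P[3*i+2]);
  }
  const int reach = 2;                 // bins of cutoff/2, scan +/-2
  double bs = cutoff / reach;
  int nbx = std::max(1, (int)std::floor((maxx - minx) / bs) + 1);
  int nby = std::max(1, (int)std::floor((maxy - miny) / bs) + 1);
  int nbz = std::max(1, (int)std::floor((maxz - minz) / bs) + 1);
  size_t nbins = (size_t)nbx * nby * nbz;
  // counting sort of elements into bins (flat arrays, no per-bin vectors)
  std::vector<int> binof(n), start(nbins + 1, 0), order(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(nbx - 1, (int)std::floor((P[3*i] - minx) / bs));
    int iy = std::min(nby - 1, (int)std::floor((P[3*i+1] - miny) / bs));
    int iz = std::min(nbz - 1, (int)std::floor((P[3*i+2] - minz) / bs));
    binof[i] = ix + nbx * (iy + nby * iz);
    ++start[binof[i] + 1];
  }
  for (size_t b = 0; b < nbins; ++b) start[b + 1] += start[b];
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int i = 0; i < n; ++i) order[fill[binof[i]]++] = i;
  double c2 = cutoff * cutoff;
  // half stencil: same bin (j > i) plus lexicographically later bins
  for (int bz0 = 0; bz0 < nbz; ++bz0)
    for (int by0 = 0; by0 < nby; ++by0)
      for (int bx0 = 0; bx0 < nbx; ++bx0) {
        size_t b = bx0 + (size_t)nbx * (by0 + (size_t)nby * bz0);
        int s0 = start[b], e0 = start[b + 1];
        if (s0 == e0) continue;
        for (int dz = 0; dz <= reach; ++dz) {
          int iz = bz0 + dz; if (iz >= nbz) continue;
          int dymin = (dz == 0) ? 0 : -reach;
          for (int dy = dymin; dy <= reach; ++dy) {
            int iy = by0 + dy; if (iy < 0 || iy >= nby) continue;
            int dxmin = (dz == 0 && dy == 0) ? 0 : -reach;
            for (int dx = dxmin; dx <= reach; ++dx) {
              int ix = bx0 + dx; if (ix < 0 || ix >= nbx) continue;
              bool samebin = (dx == 0 && dy == 0 && dz == 0);
              size_t b2 = ix + (size_t)nbx * (iy + (size_t)nby * iz);
              int s1 = start[b2], e1 = start[b2 + 1];
              for (int q0 = s0; q0 < e0; ++q0) {
                int i = order[q0];
                double xi = P[3*i], yi = P[3*i+1], zi = P[3*i+2];
                int ci = cell[i];
                int qstart = samebin ? q0 + 1 : s1;
                for (int q1 = qstart; q1 < e1; ++q1) {
                  int j = order[q1];
                  if (cell[j] == ci) continue;
                  double ddx = xi - P[3*j], ddy = yi - P[3*j+1],
                         ddz = zi - P[3*j+2];
                  if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                    out.a.push_back(i); out.b.push_back(j);
                  }
                }
              }
            }
          }
        }
      }
}

// potential forces only (intra + inter + wall); used directly by tests and
// shared by the integrator
static void accumulate_forces(const std::vector<double> &P,
                              const std::vector<int> &cell,
                              const std::vector<std::vector<int> > &members,
                              const PairList &pairs,
                              double mu, double r0, double eps, double sigma,
                              double ljcut, double capr, double epsw,
                              double wallcut, double R, double H,
                              std::vector<double> &F,
                              std::vector<double> &wdist) {
  int n = (int)P.size() / 3;
  std::fill(F.begin(), F.end(), 0.0);
  // intra: all element pairs of each cell, no cutoff
  for (size_t c = 0; c < members.size(); ++c) {
    const std::vector<int> &m = members[c];
    for (size_t a = 0; a + 1 < m.size(); ++a) {
      for (size_t b = a + 1; b < m.size(); ++b) {
        int i = m[a], j = m[b];
        double dx = P[3*i] - P[3*j], dy = P[3*i+1] - P[3*j+1],
               dz = P[3*i+2] - P[3*j+2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-12)
          stop("coincident elements within a cell: spring direction undefined");
        double f = -mu * (r - r0) / r;  // along (ri - rj)
        F[3*i] += f * dx; F[3*i+1] += f * dy; F[3*i+2] += f * dz;
        F[3*j] -= f * dx; F[3*j+1] -= f * dy; F[3*j+2] -= f * dz;
      }
    }
  }
  // inter: Lennard-Jones within the hard cutoff, repulsion capped below
  // capr. Computed in r^2 form: F_vec = g(r^2) * d with
  // g = (eps/sigma^2) q2 (12 q6^2 - 6 q6), q2 = sigma^2/r^2 (no sqrt).
  double lc2 = ljcut * ljcut;
  double cap2 = capr * capr;
  double sigma2 = sigma * sigma;
  double eps_s2 = eps / sigma2;
  for (size_t k = 0; k < pairs.a.size(); ++k) {
    int i = pairs.a[k], j = pairs.b[k];
    double dx = P[3*i] - P[3*j], dy = P[3*i+1] - P[3*j+1],
           dz = P[3*i+2] - P[3*j+2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > lc2) continue;
    double gx, gy, gz;
    if (r2 < cap2) {
      // rare: deep overlap, constant capped magnitude along the unit vector
      double r = std::sqrt(r2);
      double ux, uy, uz;
      if (r < 1e-12) { ux = 1.0; uy = 0.0; uz = 0.0; }
      else { ux = dx / r; uy = dy / r; uz = dz / r; }
      double f = lj_force_mag(capr, eps, sigma);
      gx = f * ux; gy = f * uy; gz = f * uz;
    } else {
      double q2 = sigma2 / r2;
      double q6 = q2 * q2 * q2;
      double g = eps_s2 * q2 * (12.0 * q6 * q6 - 6.0 * q6);
      gx = g * dx; gy = g * dy; gz = g * dz;
    }
    F[3*i] += gx; F[3*i+1] += gy; F[3*i+2] += gz;
    F[3*j] -= gx; F[3*j+1] -= gy; F[3*j+2] -= gz;
  }
  // wall adhesion: F = eps_external * (foot - p) within wallcut of the wall
  for (int i = 0; i < n; ++i) {
    SurfHit h = surf_query(P[3*i], P[3*i+1], P[3*i+2], R, H);
    wdist[i] = h.dist;
    if (h.dist <= wallcut) {
      F[3*i]   += epsw * (h.fx - P[3*i]);
      F[3*i+1] += epsw * (h.fy - P[3*i+1]);
      F[3*i+2] += epsw * (h.fz - P[3*i+2]);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_compute_forces(NumericMatrix pos, IntegerVector el_cell,
                                 List par) {
  int n = pos.nrow();
  std::vector<double> P(3 * (size_t)n);
  std::vector<int> cell(n);
  int ncell = 0;
  for (int i = 0; i < n; ++i) {
    P[3*i] = pos(i, 0); P[3*i+1] = pos(i, 1); P[3*i+2] = pos(i, 2);
    cell[i] = el_cell[i] - 1;
    ncell = std::max(ncell, el_cell[i]);
  }
  std::vector<std::vector<int> > members(ncell);
  for (int i = 0; i < n; ++i) members[cell[i]].push_back(i);
  PairList pairs;
  double ljcut = as<double>(par["lj_cutoff"]);
  find_pairs(P, cell, ljcut, pairs);
  std::vector<double> F(3 * (size_t)n), wd(n);
  accumulate_forces(P, cell, members, pairs,
                    as<double>(par["mu"]), as<double>(par["r0"]),
                    as<double>(par["eps_lj"]), as<double>(par["sigma_lj"]),
                    ljcut, as<double>(par["cap_r"]),
                    as<double>(par["eps_external"]),
                    as<double>(par["wall_cutoff"]),
                    as<double>(par["R"]), as<double>(par["H"]),
                    F, wd);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = F[3*i]; out(i, 1) = F[3*i+1]; out(i, 2) = F[3*i+2];
  }
  return out;
}

// Overdamped integrator: nsteps forward-Euler updates with a Verlet pair
// list (skin-based rebuild). paneth[c] marks cells with active downhill
// migration at speed pspeed; drag rescales the provisional z-velocity of
// near-wall elements by (1 + bz). The rigid wall is impenetrable: elements
// that cross it are projected back to the surface.
// [[Rcpp::export]]
NumericMatrix cpp_mech_advance(NumericMatrix pos, IntegerVector el_cell,
                               LogicalVector paneth, List par, int nsteps,
                               double dt) {
  int n = pos.nrow();
  if (n == 0) return pos;
  std::vector<double> P(3 * (size_t)n);
  std::vector<int> cell(n);
  int ncell = paneth.size();
  for (int i = 0; i < n; ++i) {
    P[3*i] = pos(i, 0); P[3*i+1] = pos(i, 1); P[3*i+2] = pos(i, 2);
    cell[i] = el_cell[i] - 1;
    if (cell[i] < 0 || cell[i] >= ncell) stop("element cell index out of range");
  }
  std::vector<std::vector<int> > members(ncell);
  for (int i = 0; i < n; ++i) members[cell[i]].push_back(i);

  double mu = as<double>(par["mu"]), r0 = as<double>(par["r0"]);
  double eps = as<double>(par["eps_lj"]), sigma = as<double>(par["sigma_lj"]);
  double ljcut = as<double>(par["lj_cutoff"]), capr = as<double>(par["cap_r"]);
  double epsw = as<double>(par["eps_external"]);
  double wallcut = as<double>(par["wall_cutoff"]);
  double bz = as<double>(par["b_z"]);
  double mob = as<double>(par["mobility"]);
  double max_step = as<double>(par["max_step"]);
  double pspeed = as<double>(par["paneth_speed"]);
  double R = as<double>(par["R"]), H = as<double>(par["H"]);
  double skin = as<double>(par["skin"]);

  PairList pairs;
  std::vector<double> Pref(3 * (size_t)n);  // positions at last (re)scan
  bool need_build = true;
  std::vector<double> F(3 * (size_t)n), wd(n);

  std::vector<int> orig(n), order, newcell(n);
  std::vector<double> newP(3 * (size_t)n);
  for (int i = 0; i < n; ++i) orig[i] = i;
  std::vector<char> moved(n, 0);
  std::vector<int> movers;
  double half_skin = 0.5 * skin, half_skin2 = 0.25 * skin * skin;
  double list_cut = ljcut + skin, list_cut2 = list_cut * list_cut;

  for (int s = 0; s < nsteps; ++s) {
    if (need_build) {
      // full rebuild: re-sort elements spatially, then build the pair
      // list on the sorted layout (cache-local force loop)
      spatial_order(P, list_cut / 2.0, order);
      std::vector<int> neworig(n);
      for (int q = 0; q < n; ++q) {
        int i = order[q];
        newP[3*q] = P[3*i]; newP[3*q+1] = P[3*i+1]; newP[3*q+2] = P[3*i+2];
        newcell[q] = cell[i];
        neworig[q] = orig[i];
      }
      P.swap(newP); cell.swap(newcell); orig.swap(neworig);
      for (int c = 0; c < ncell; ++c) members[c].clear();
      for (int i = 0; i < n; ++i) members[cell[i]].push_back(i);
      find_pairs(P, cell, list_cut, pairs);
      Pref = P;
      need_build = false;
    } else if (!movers.empty()) {
      // incremental maintenance: pairs were captured with both ends fresh
      // (full rebuild) or with a widened cutoff (mover rescan below), so a
      // pair can only be stale if one of its ends moved more than half a
      // skin since its last scan; drop pairs touching movers and rescan
      // just the movers against a fresh spatial hash
      for (size_t k = 0; k < movers.size(); ++k) moved[movers[k]] = 1;
      size_t w = 0;
      for (size_t k = 0; k < pairs.a.size(); ++k) {
        if (!moved[pairs.a[k]] && !moved[pairs.b[k]]) {
          pairs.a[w] = pairs.a[k]; pairs.b[w] = pairs.b[k]; ++w;
        }
      }
      pairs.a.resize(w); pairs.b.resize(w);
      {
        // widened capture radius: the partner of a rescanned pair may
        // already sit half a skin from its own reference, so scan to
        // ljcut + 1.5 skin to keep the half-skin trigger sufficient
        double minx = P[0], miny = P[1], minz = P[2];
        double maxx = P[0], maxy = P[1], maxz = P[2];
        for (int i = 1; i < n; ++i) {
          minx = std::min(minx, P[3*i]);   maxx = std::max(maxx, P[3*i]);
          miny = std::min(miny, P[3*i+1]); maxy = std::max(maxy, P[3*i+1]);
          minz = std::min(minz, P[3*i+2]); maxz = std::max(maxz, P[3*i+2]);
        }
        double bs = ljcut + 1.5 * skin;
        double bs2 = bs * bs;
        int nbx = std::max(1, (int)std::floor((maxx - minx) / bs) + 1);
        int nby = std::max(1, (int)std::floor((maxy - miny) / bs) + 1);
        int nbz = std::max(1, (int)std::floor((maxz - minz) / bs) + 1);
        size_t nbins = (size_t)nbx * nby * nbz;
        std::vector<int> start(nbins + 1, 0), binof(n), items(n);
        for (int i = 0; i < n; ++i) {
          int ix = std::min(nbx - 1, (int)std::floor((P[3*i] - minx) / bs));
          int iy = std::min(nby - 1, (int)std::floor((P[3*i+1] - miny) / bs));
          int iz = std::min(nbz - 1, (int)std::floor((P[3*i+2] - minz) / bs));
          binof[i] = ix + nbx * (iy + nby * iz);
          ++start[binof[i] + 1];
        }
        for (size_t b = 0; b < nbins; ++b) start[b + 1] += start[b];
        std::vector<int> fill(start.begin(), start.end() - 1);
        for (int i = 0; i < n; ++i) items[fill[binof[i]]++] = i;
        for (size_t k = 0; k < movers.size(); ++k) {
          int i = movers[k];
          int bx = binof[i] % nbx, by = (binof[i] / nbx) % nby,
              bz2 = binof[i] / (nbx * nby);
          for (int dz = -1; dz <= 1; ++dz) {
            int iz = bz2 + dz; if (iz < 0 || iz >= nbz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int iy = by + dy; if (iy < 0 || iy >= nby) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                int ix = bx + dx; if (ix < 0 || ix >= nbx) continue;
                size_t b = ix + (size_t)nbx * (iy + (size_t)nby * iz);
                for (int q = start[b]; q < start[b + 1]; ++q) {
                  int j = items[q];
                  if (j == i || cell[j] == cell[i]) continue;
                  // mover-mover pairs once
                  if (moved[j] && j < i) continue;
                  double ddx = P[3*i] - P[3*j], ddy = P[3*i+1] - P[3*j+1],
                         ddz = P[3*i+2] - P[3*j+2];
                  if (ddx * ddx + ddy * ddy + ddz * ddz < bs2) {
                    pairs.a.push_back(i); pairs.b.push_back(j);
                  }
                }
              }
            }
          }
          Pref[3*i] = P[3*i]; Pref[3*i+1] = P[3*i+1]; Pref[3*i+2] = P[3*i+2];
        }
        // clear flags only after every mover has been rescanned: the
        // moved[] marks are what keeps mover-mover pairs deduplicated
        for (size_t k = 0; k < movers.size(); ++k) moved[movers[k]] = 0;
      }
    }
    accumulate_forces(P, cell, members, pairs, mu, r0, eps, sigma,
                      ljcut, capr, epsw, wallcut, R, H, F, wd);
    movers.clear();
    for (int i = 0; i < n; ++i) {
      double vx = mob * F[3*i], vy = mob * F[3*i+1], vz = mob * F[3*i+2];
      if (pspeed != 0.0 && paneth[cell[i]]) {
        double tx, ty, tz;
        downhill(P[3*i], P[3*i+1], P[3*i+2], R, H, tx, ty, tz);
        vx += pspeed * tx; vy += pspeed * ty; vz += pspeed * tz;
      }
      if (wd[i] <= wallcut) vz *= (1.0 + bz);   // near-wall vertical drag
      if (!std::isfinite(vx) || !std::isfinite(vy) || !std::isfinite(vz))
        stop("non-finite force encountered during integration");
      double sx2 = dt * vx, sy2 = dt * vy, sz2 = dt * vz;
      double sl = std::sqrt(sx2 * sx2 + sy2 * sy2 + sz2 * sz2);
      if (sl > max_step) {        // clamp transients (capped LJ overlaps)
        double sc = max_step / sl;
        sx2 *= sc; sy2 *= sc; sz2 *= sc;
      }
      double x = P[3*i] + sx2, y = P[3*i+1] + sy2, z = P[3*i+2] + sz2;
      // impenetrable wall: project escaped elements back inside
      if (z > R) {
        double rho2 = x * x + y * y;
        if (rho2 > R * R) {
          double sc = (R - 1e-6) / std::sqrt(rho2);
          x *= sc; y *= sc;
        }
      } else {
        double dxc = x, dyc = y, dzc = z - R;
        double rad2 = dxc * dxc + dyc * dyc + dzc * dzc;
        if (rad2 > R * R) {
          double sc = (R - 1e-6) / std::sqrt(rad2);
          x = dxc * sc; y = dyc * sc; z = R + dzc * sc;
        }
      }
      P[3*i] = x; P[3*i+1] = y; P[3*i+2] = z;
      double ddx = x - Pref[3*i], ddy = y - Pref[3*i+1],
             ddz = z - Pref[3*i+2];
      if (ddx * ddx + ddy * ddy + ddz * ddz > half_skin2)
        movers.push_back(i);
    }
    // many movers: cheaper to re-sort and rebuild outright
    if ((int)movers.size() > n / 6) { need_build = true; movers.clear(); }
  }
  NumericMatrix out(n, 3);
  for (int q = 0; q < n; ++q) {
    int i = orig[q];
    out(i, 0) = P[3*q]; out(i, 1) = P[3*q+1]; out(i, 2) = P[3*q+2];
  }
  return out;
}

// Unique pairs of distinct cells having at least one element pair within
// `dist`; returned as a 2-column matrix of 1-based cell indices (a < b).
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, IntegerVector el_cell,
                                double dist) {
  int n = pos.nrow();
  std::vector<double> P(3 * (size_t)n);
  std::vector<int> cell(n);
  for (int i = 0; i < n; ++i) {
    P[3*i] = pos(i, 0); P[3*i+1] = pos(i, 1); P[3*i+2] = pos(i, 2);
    cell[i] = el_cell[i] - 1;
  }
  PairList pairs;
  find_pairs(P, cell, dist, pairs);
  std::set<std::pair<int, int> > seen;
  for (size_t k = 0; k < pairs.a.size(); ++k) {
    int ca = cell[pairs.a[k]], cb = cell[pairs.b[k]];
    if (ca > cb) std::swap(ca, cb);
    seen.insert(std::make_pair(ca, cb));
  }
  IntegerMatrix out((int)seen.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::iterator it = seen.begin();
       it != seen.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;
    out(r, 1) = it->second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Regular-grid chemistry support. Node (i,j,k) maps to index
// i + nx*(j + ny*k), matching R's array layout with dim = c(nx, ny, nz).
// ---------------------------------------------------------------------------

// cloud-in-cell (trilinear) deposition of per-point weights onto grid nodes
// [[Rcpp::export]]
NumericVector cpp_trilinear_deposit(NumericMatrix pos, NumericVector w,
                                    NumericVector origin, double h,
                                    IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int p = 0; p < pos.nrow(); ++p) {
    double gx = (pos(p, 0) - origin[0]) / h;
    double gy = (pos(p, 1) - origin[1]) / h;
    double gz = (pos(p, 2) - origin[2]) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
        k0 = (int)std::floor(gz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 ||
        k0 >= nz - 1) {
      // allow points exactly on the upper faces
      if (gx >= 0 && gy >= 0 && gz >= 0 && gx <= nx - 1 && gy <= ny - 1 &&
          gz <= nz - 1) {
        i0 = std::min(i0, nx - 2); j0 = std::min(j0, ny - 2);
        k0 = std::min(k0, nz - 2);
      } else {
        stop("point outside the grid box");
      }
    }
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          double wt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                      (dk ? fz : 1 - fz);
          out[(i0 + di) + (R_xlen_t)nx * ((j0 + dj) + (R_xlen_t)ny * (k0 + dk))] +=
            w[p] * wt;
        }
  }
  return out;
}

// trilinear interpolation of a grid field at arbitrary points
// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector field, IntegerVector dim,
                                   NumericVector origin, double h,
                                   NumericMatrix pos) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(pos.nrow());
  for (int p = 0; p < pos.nrow(); ++p) {
    double gx = (pos(p, 0) - origin[0]) / h;
    double gy = (pos(p, 1) - origin[1]) / h;
    double gz = (pos(p, 2) - origin[2]) / h;
    if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 ||
        gz > nz - 1)
      stop("point outside the grid box");
    int i0 = std::min((int)std::floor(gx), nx - 2);
    int j0 = std::min((int)std::floor(gy), ny - 2);
    int k0 = std::min((int)std::floor(gz), nz - 2);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int di = 0; di <= (nx > 1 ? 1 : 0); ++di)
      for (int dj = 0; dj <= (ny > 1 ? 1 : 0); ++dj)
        for (int dk = 0; dk <= (nz > 1 ? 1 : 0); ++dk) {
          double wt = (di ? fx : (nx > 1 ? 1 - fx : 1.0)) *
                      (dj ? fy : (ny > 1 ? 1 - fy : 1.0)) *
                      (dk ? fz : (nz > 1 ? 1 - fz : 1.0));
          acc += wt * field[(i0 + di) +
                            (R_xlen_t)nx * ((j0 + dj) + (R_xlen_t)ny * (k0 + dk))];
        }
    out[p] = acc;
  }
  return out;
}

// Forward-Euler / central-difference stepping of
//   dc/dt = div(D grad c) + S - d*c
// with harmonic-mean face diffusivities (a zero-diffusivity node seals its
// faces, so exterior nodes exchange no mass) and zero-flux box boundaries.
// Concentrations are clamped at zero; exterior (mask==0) nodes stay zero.
// [[Rcpp::export]]
NumericVector cpp_ftcs(NumericVector c0, NumericVector D, IntegerVector mask,
                       NumericVector S, IntegerVector dim, double h,
                       double dt, int substeps, double decay) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(c0.begin(), c0.end()), nxt(n);
  double ih2 = 1.0 / (h * h);
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int s = 0; s < substeps; ++s) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t idx = i + sy * j + sz * k;
          if (!mask[idx]) { nxt[idx] = 0.0; continue; }
          double Di = D[idx];
          double lap = 0.0;
          if (Di > 0.0) {
            R_xlen_t nb[6];
            int nnb = 0;
            if (i > 0) nb[nnb++] = idx - sx;
            if (i < nx - 1) nb[nnb++] = idx + sx;
            if (j > 0) nb[nnb++] = idx - sy;
            if (j < ny - 1) nb[nnb++] = idx + sy;
            if (k > 0) nb[nnb++] = idx - sz;
            if (k < nz - 1) nb[nnb++] = idx + sz;
            for (int q = 0; q < nnb; ++q) {
              double Dj = D[nb[q]];
              if (Dj > 0.0) {
                double Df = 2.0 * Di * Dj / (Di + Dj);
                lap += Df * (cur[nb[q]] - cur[idx]);
              }
            }
            lap *= ih2;
          }
          double v = cur[idx] + dt * (lap + S[idx] - decay * cur[idx]);
          nxt[idx] = (v > 0.0) ? v : 0.0;
        }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// minimum of `values` within each 1-based group (groups without members
// keep +Inf); used for per-cell minimum wall distances
// [[Rcpp::export]]
NumericVector cpp_group_min(NumericVector values, IntegerVector group,
                            int ngroups) {
  NumericVector out(ngroups, R_PosInf);
  for (int i = 0; i < values.size(); ++i) {
    int g = group[i] - 1;
    if (values[i] < out[g]) out[g] = values[i];
  }
  return out;
}
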