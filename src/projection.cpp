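// Cone back-projection kernels: voxel traversal (Amanatides-Woo style DDA)
// and per-event system-matrix row assembly.  Conventions match the R side:
// voxel linear index j = ix + nx*(iy + ny*iz), 0-based, half-open voxel
// boundaries [low, high).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Grid {
  double o[3], s[3];
  int d[3];
  Grid(NumericVector origin, NumericVector spacing, IntegerVector dims) {
    for (int k = 0; k < 3; ++k) {
      o[k] = origin[k]; s[k] = spacing[k]; d[k] = dims[k];
    }
  }
  int lin(const int ix[3]) const {
    return ix[0] + d[0] * (ix[1] + d[1] * ix[2]);
  }
};

// Clip segment p1->p2 (parameter t in [0,1]) to the grid box; returns false
// if no intersection.  On return t0 < t1.
static bool clipToGrid(const double p1[3], const double dir[3],
                       const Grid &g, double &t0, double &t1) {
  t0 = 0.0; t1 = 1.0;
  for (int k = 0; k < 3; ++k) {
    double lo = g.o[k], hi = g.o[k] + g.s[k] * g.d[k];
    if (std::fabs(dir[k]) < 1e-300) {
      if (p1[k] < lo || p1[k] >= hi) return false;
    } else {
      double ta = (lo - p1[k]) / dir[k];
      double tb = (hi - p1[k]) / dir[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// Ordered voxel traversal of the segment p1->p2 clipped to the grid.
static void traverse(const double p1[3], const double p2[3], const Grid &g,
                     std::vector<int> &vox, std::vector<double> &len) {
  double dir[3];
  for (int k = 0; k < 3; ++k) dir[k] = p2[k] - p1[k];
  double L = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  if (L <= 0) return;
  double t0, t1;
  if (!clipToGrid(p1, dir, g, t0, t1)) return;

  // entry voxel, nudged inside
  double tmid = t0 + 1e-12 * (t1 - t0);
  int ix[3], step[3];
  double tMax[3], tDelta[3];
  for (int k = 0; k < 3; ++k) {
    double x = p1[k] + tmid * dir[k];
    int i = (int)std::floor((x - g.o[k]) / g.s[k]);
    if (i < 0) i = 0;
    if (i >= g.d[k]) i = g.d[k] - 1;
    ix[k] = i;
    if (dir[k] > 0) {
      step[k] = 1;
      tMax[k] = (g.o[k] + (i + 1) * g.s[k] - p1[k]) / dir[k];
      tDelta[k] = g.s[k] / dir[k];
    } else if (dir[k] < 0) {
      step[k] = -1;
      tMax[k] = (g.o[k] + i * g.s[k] - p1[k]) / dir[k];
      tDelta[k] = -g.s[k] / dir[k];
    } else {
      step[k] = 0;
      tMax[k] = R_PosInf;
      tDelta[k] = R_PosInf;
    }
  }

  double tcur = t0;
  while (tcur < t1 - 1e-15) {
    int kmin = 0;
    if (tMax[1] < tMax[kmin]) kmin = 1;
    if (tMax[2] < tMax[kmin]) kmin = 2;
    double tnext = std::min(tMax[kmin], t1);
    double seg = (tnext - tcur) * L;
    if (seg > 0) {
      vox.push_back(g.lin(ix));
      len.push_back(seg);
    }
    tcur = tnext;
    if (tMax[kmin] >= t1) break;
    ix[kmin] += step[kmin];
    if (ix[kmin] < 0 || ix[kmin] >= g.d[kmin]) break;
    tMax[kmin] += tDelta[kmin];
  }
}

// [[Rcpp::export(name = ".ray_path_cpp")]]
List ray_path_cpp(NumericVector p1, NumericVector p2, NumericVector origin,
                  NumericVector spacing, IntegerVector dims) {
  Grid g(origin, spacing, dims);
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {p2[0], p2[1], p2[2]};
  std::vector<int> vox;
  std::vector<double> len;
  traverse(a, b, g, vox, len);
  return List::create(_["voxel"] = wrap(vox), _["length"] = wrap(len));
}

// Chord length of the voxel box through its center along direction u.
static double voxelChord(const double u[3], const Grid &g) {
  double tlo = -R_PosInf, thi = R_PosInf;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(u[k]) > 1e-300) {
      double h = 0.5 * g.s[k] / std::fabs(u[k]);
      if (-h > tlo) tlo = -h;
      if (h < thi) thi = h;
    }
  }
  return thi - tlo;
}

// Optical depth along segment from point c to apex through the mu map,
// accumulated in place (same traversal as traverse(), no allocation).
static double opticalDepth(const double p1[3], const double p2[3],
                           const Grid &g, const double *mu) {
  double dir[3];
  for (int k = 0; k < 3; ++k) dir[k] = p2[k] - p1[k];
  double L = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  if (L <= 0) return 0.0;
  double t0, t1;
  if (!clipToGrid(p1, dir, g, t0, t1)) return 0.0;
  double tmid = t0 + 1e-12 * (t1 - t0);
  int ix[3], step[3];
  double tMax[3], tDelta[3];
  for (int k = 0; k < 3; ++k) {
    double x = p1[k] + tmid * dir[k];
    int i = (int)std::floor((x - g.o[k]) / g.s[k]);
    if (i < 0) i = 0;
    if (i >= g.d[k]) i = g.d[k] - 1;
    ix[k] = i;
    if (dir[k] > 0) {
      step[k] = 1;
      tMax[k] = (g.o[k] + (i + 1) * g.s[k] - p1[k]) / dir[k];
      tDelta[k] = g.s[k] / dir[k];
    } else if (dir[k] < 0) {
      step[k] = -1;
      tMax[k] = (g.o[k] + i * g.s[k] - p1[k]) / dir[k];
      tDelta[k] = -g.s[k] / dir[k];
    } else {
      step[k] = 0;
      tMax[k] = R_PosInf;
      tDelta[k] = R_PosInf;
    }
  }
  double od = 0.0, tcur = t0;
  while (tcur < t1 - 1e-15) {
    int kmin = 0;
    if (tMax[1] < tMax[kmin]) kmin = 1;
    if (tMax[2] < tMax[kmin]) kmin = 2;
    double tnext = std::min(tMax[kmin], t1);
    od += mu[g.lin(ix)] * (tnext - tcur) * L;
    tcur = tnext;
    if (tMax[kmin] >= t1) break;
    ix[kmin] += step[kmin];
    if (ix[kmin] < 0 || ix[kmin] >= g.d[kmin]) break;
    tMax[kmin] += tDelta[kmin];
  }
  return od;
}

// Assemble sparse system-matrix rows for a batch of Compton cones.
// apex, axis: m x 3; halfAngle: m.  mu: per-voxel attenuation (1/mm).
// Returns triplets (1-based i, 1-based j, value) after applying the
// row-relative floor.  survBound is a lower bound on any survival factor,
// used to skip attenuation traces that cannot pass the floor.
// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(NumericMatrix apex, NumericMatrix axis,
                  NumericVector halfAngle, NumericVector origin,
                  NumericVector spacing, IntegerVector dims,
                  NumericVector mu, double sigma, double floorRel,
                  double ellRef, bool deposition, double survBound) {
  Grid g(origin, spacing, dims);
  const int m = apex.nrow();
  const int M = g.d[0] * g.d[1] * g.d[2];
  bool anyMu = false;
  for (int j = 0; j < M; ++j) if (mu[j] > 0) { anyMu = true; break; }

  std::vector<int> outI, outJ;
  std::vector<double> outX;
  std::vector<double> u(M), d2(M);
  std::vector<double> cx(M), cy(M), cz(M);

  // voxel centers once
  {
    int j = 0;
    for (int iz = 0; iz < g.d[2]; ++iz)
      for (int iy = 0; iy < g.d[1]; ++iy)
        for (int ixx = 0; ixx < g.d[0]; ++ixx, ++j) {
          cx[j] = g.o[0] + (ixx + 0.5) * g.s[0];
          cy[j] = g.o[1] + (iy + 0.5) * g.s[1];
          cz[j] = g.o[2] + (iz + 0.5) * g.s[2];
        }
  }

  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double *muP = REAL(mu);

  // Bounds used to prune the cheap pass without changing the result:
  // within one row, a_j / a_max >= (w_j / w_max) * (dep_j / dep_max)
  //                               * survival_j,
  // and dep_j / dep_max >= hmin / voxel diagonal (the chord through the
  // voxel center lies in [hmin, diag]), survival_j >= survBound.  So any
  // voxel with w_j / w_max below floorRel * survBound * hmin/diag cannot
  // pass the row floor and is skipped before the exp/chord/trace work.
  double hmin = g.s[0], diagVox = 0.0;
  for (int k = 0; k < 3; ++k) {
    if (g.s[k] < hmin) hmin = g.s[k];
    diagVox += g.s[k] * g.s[k];
  }
  diagVox = std::sqrt(diagVox);
  // global bounds on the deposition factor over all voxels and chords
  double depLo = R_PosInf, depHi = 0.0;
  for (int j = 0; j < M; ++j) {
    double lo, hi;
    if (deposition) {
      lo = (mu[j] > 0) ? (1.0 - std::exp(-mu[j] * hmin)) : (hmin / ellRef);
      hi = (mu[j] > 0) ? (1.0 - std::exp(-mu[j] * diagVox))
                       : (diagVox / ellRef);
    } else {
      lo = mu[j] * hmin; hi = mu[j] * diagVox;
    }
    if (lo < depLo) depLo = lo;
    if (hi > depHi) depHi = hi;
  }
  double margin = (depHi > 0 && depLo > 0)
    ? floorRel * (anyMu ? survBound : 1.0) * (depLo / depHi) : 0.0;
  // delta^2 pruning radius relative to the smallest angular residual
  double d2band = (margin > 0)
    ? 2.0 * sigma * sigma * std::log(1.0 / margin) : R_PosInf;

  std::vector<int> candJ;
  std::vector<double> candA;
  for (int i = 0; i < m; ++i) {
    const double ap[3] = {apex(i, 0), apex(i, 1), apex(i, 2)};
    const double ax[3] = {axis(i, 0), axis(i, 1), axis(i, 2)};
    const double th = halfAngle[i];

    // cheap pass: squared angular residuals only
    double d2min = R_PosInf;
    for (int j = 0; j < M; ++j) {
      double dx = cx[j] - ap[0], dy = cy[j] - ap[1], dz = cz[j] - ap[2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 <= 0) { d2[j] = R_PosInf; continue; }
      double ca = (dx*ax[0] + dy*ax[1] + dz*ax[2]) / std::sqrt(r2);
      if (ca > 1) ca = 1; else if (ca < -1) ca = -1;
      double delta = std::acos(ca) - th;
      d2[j] = delta * delta;
      if (d2[j] < d2min) d2min = d2[j];
    }
    if (!R_FINITE(d2min)) continue;
    double d2cut = d2min + d2band;

    double umax = 0.0;
    for (int j = 0; j < M; ++j) {
      if (d2[j] > d2cut) { u[j] = 0.0; continue; }
      double w = std::exp(-d2[j] * inv2s2);
      double dx = cx[j] - ap[0], dy = cy[j] - ap[1], dz = cz[j] - ap[2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dirv[3] = {-dx / r, -dy / r, -dz / r};
      double ell = voxelChord(dirv, g);
      double dep;
      if (deposition)
        dep = (mu[j] > 0) ? (1.0 - std::exp(-mu[j] * ell)) : (ell / ellRef);
      else
        dep = mu[j] * ell;
      u[j] = w * dep;
      if (u[j] > umax) umax = u[j];
    }
    if (umax <= 0) continue;

    // attenuation survival only where the entry could pass the floor
    double cutoff = floorRel * umax * (anyMu ? survBound : 1.0);
    double amax = 0.0;
    candJ.clear();
    candA.clear();
    for (int j = 0; j < M; ++j) {
      if (u[j] < cutoff || u[j] <= 0) continue;
      double a = u[j];
      if (anyMu) {
        const double c[3] = {cx[j], cy[j], cz[j]};
        a *= std::exp(-opticalDepth(c, ap, g, muP));
      }
      candJ.push_back(j);
      candA.push_back(a);
      if (a > amax) amax = a;
    }
    double keep = floorRel * amax;
    for (size_t q = 0; q < candJ.size(); ++q) {
      if (candA[q] >= keep && candA[q] > 0) {
        outI.push_back(i + 1);
        outJ.push_back(candJ[q] + 1);
        outX.push_back(candA[q]);
      }
    }
  }
  return List::create(_["i"] = wrap(outI), _["j"] = wrap(outJ),
                      _["x"] = wrap(outX));
}

// CSR kernels for the event-by-voxel matrix (0-based p/j slots as in
// Matrix::dgRMatrix).

// [[Rcpp::export(name = ".csr_matvec")]]
NumericVector csr_matvec(IntegerVector p, IntegerVector j, NumericVector x,
                         NumericVector v) {
  const int m = p.size() - 1;
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    double s = 0.0;
    for (int q = p[r]; q < p[r + 1]; ++q) s += x[q] * v[j[q]];
    out[r] = s;
  }
  return out;
}

// [[Rcpp::export(name = ".csr_tmatvec")]]
NumericVector csr_tmatvec(IntegerVector p, IntegerVector j, NumericVector x,
                          NumericVector v, int ncol) {
  const int m = p.size() - 1;
  NumericVector out(ncol);
  for (int r = 0; r < m; ++r) {
    double vr = v[r];
    if (vr == 0.0) continue;
    for (int q = p[r]; q < p[r + 1]; ++q) out[j[q]] += x[q] * vr;
  }
  return out;
}

// [[Rcpp::export(name = ".csr_colsums")]]
NumericVector csr_colsums(IntegerVector p, IntegerVector j, NumericVector x,
                          int ncol) {
  NumericVector out(ncol);
  const int nnz = x.size();
  for (int q = 0; q < nnz; ++q) out[j[q]] += x[q];
  return out;
}
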