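// Low-level kernels for the SPC/E water MD engine: minimum-image pair lists
// (atom- and group-based), cubic-Hermite evaluation of tabulated pair
// potentials, direct Ewald summation, SHAKE/RATTLE, the velocity-Verlet /
// Nose-Hoover integrator, and binned pair statistics for the observables.
//
// Unit system throughout: kJ/mol, nm, ps, atomic mass unit, elementary charge.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  double t = d / L;
  // round-half-away-from-zero via int cast: far cheaper than the libm
  // rounding calls on baseline x86-64, exact for any |t| < 2^31
  t -= (double)(long long)(t >= 0 ? t + 0.5 : t - 0.5);
  return t * L;
}

// ---------------------------------------------------------------------------
// pair lists
// ---------------------------------------------------------------------------

// Geometric centres of charge groups, built from minimum-image displacements
// relative to each group's first atom so that wrapped molecules stay intact.
static void group_centres(const NumericMatrix& pos, const IntegerVector& group_id,
                          const NumericVector& box, int ngrp,
                          std::vector<double>& cx, std::vector<double>& cy,
                          std::vector<double>& cz,
                          std::vector<std::vector<int> >& members) {
  int n = pos.nrow();
  members.assign(ngrp, std::vector<int>());
  for (int i = 0; i < n; ++i) members[group_id[i] - 1].push_back(i);
  cx.assign(ngrp, 0.0); cy.assign(ngrp, 0.0); cz.assign(ngrp, 0.0);
  for (int g = 0; g < ngrp; ++g) {
    if (members[g].empty()) continue;
    int a0 = members[g][0];
    double sx = 0, sy = 0, sz = 0;
    for (size_t k = 0; k < members[g].size(); ++k) {
      int a = members[g][k];
      sx += min_image(pos(a, 0) - pos(a0, 0), box[0]);
      sy += min_image(pos(a, 1) - pos(a0, 1), box[1]);
      sz += min_image(pos(a, 2) - pos(a0, 2), box[2]);
    }
    double m = (double)members[g].size();
    cx[g] = pos(a0, 0) + sx / m;
    cy[g] = pos(a0, 1) + sy / m;
    cz[g] = pos(a0, 2) + sz / m;
  }
}

// Enumerate reference-point pairs within r_list (closed ball), either by a
// brute-force double loop or a linked-cell sweep; result is identical.
static void point_pairs(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, const NumericVector& box,
                        double r_list, bool use_cells,
                        std::vector<std::pair<int,int> >& out) {
  int n = (int)x.size();
  double r2 = r_list * r_list;
  out.clear();
  int ncx = (int)std::floor(box[0] / r_list);
  int ncy = (int)std::floor(box[1] / r_list);
  int ncz = (int)std::floor(box[2] / r_list);
  if (!use_cells || ncx < 3 || ncy < 3 || ncz < 3) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[j] - x[i], box[0]);
        double dy = min_image(y[j] - y[i], box[1]);
        double dz = min_image(z[j] - z[i], box[2]);
        if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(std::make_pair(i, j));
      }
  } else {
    int ncell = ncx * ncy * ncz;
    std::vector<std::vector<int> > cell(ncell);
    for (int i = 0; i < n; ++i) {
      double wx = x[i] - box[0] * std::floor(x[i] / box[0]);
      double wy = y[i] - box[1] * std::floor(y[i] / box[1]);
      double wz = z[i] - box[2] * std::floor(z[i] / box[2]);
      int ix = std::min((int)(wx / box[0] * ncx), ncx - 1);
      int iy = std::min((int)(wy / box[1] * ncy), ncy - 1);
      int iz = std::min((int)(wz / box[2] * ncz), ncz - 1);
      cell[(ix * ncy + iy) * ncz + iz].push_back(i);
    }
    for (int ix = 0; ix < ncx; ++ix)
      for (int iy = 0; iy < ncy; ++iy)
        for (int iz = 0; iz < ncz; ++iz) {
          int c0 = (ix * ncy + iy) * ncz + iz;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int jx = (ix + dx + ncx) % ncx;
                int jy = (iy + dy + ncy) % ncy;
                int jz = (iz + dz + ncz) % ncz;
                int c1 = (jx * ncy + jy) * ncz + jz;
                if (c1 < c0) continue;
                for (size_t a = 0; a < cell[c0].size(); ++a)
                  for (size_t b = 0; b < cell[c1].size(); ++b) {
                    int i = cell[c0][a], j = cell[c1][b];
                    if (c0 == c1 && j <= i) continue;
                    double ddx = min_image(x[j] - x[i], box[0]);
                    double ddy = min_image(y[j] - y[i], box[1]);
                    double ddz = min_image(z[j] - z[i], box[2]);
                    if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
                      if (i < j) out.push_back(std::make_pair(i, j));
                      else out.push_back(std::make_pair(j, i));
                    }
                  }
              }
        }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }
}

// Build the atom-pair interaction list. scheme 0 = atom-based (atom-atom
// distance <= r_list, intra-group pairs excluded), scheme 1 = group-based
// (all atom pairs of every group pair whose geometric centres are within
// r_list). Pairs are returned 0-based, lexicographically sorted.
static void build_pairs(const NumericMatrix& pos, const NumericVector& box,
                        const IntegerVector& group_id, double r_list, int scheme,
                        bool use_cells, std::vector<std::pair<int,int> >& pairs) {
  int n = pos.nrow();
  pairs.clear();
  int ngrp = 0;
  for (int i = 0; i < n; ++i) ngrp = std::max(ngrp, group_id[i]);
  if (scheme == 0) {
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
    std::vector<std::pair<int,int> > raw;
    point_pairs(x, y, z, box, r_list, use_cells, raw);
    for (size_t k = 0; k < raw.size(); ++k)
      if (group_id[raw[k].first] != group_id[raw[k].second]) pairs.push_back(raw[k]);
  } else {
    std::vector<double> cx, cy, cz;
    std::vector<std::vector<int> > members;
    group_centres(pos, group_id, box, ngrp, cx, cy, cz, members);
    std::vector<std::pair<int,int> > gp;
    point_pairs(cx, cy, cz, box, r_list, use_cells, gp);
    for (size_t k = 0; k < gp.size(); ++k) {
      const std::vector<int>& A = members[gp[k].first];
      const std::vector<int>& B = members[gp[k].second];
      for (size_t a = 0; a < A.size(); ++a)
        for (size_t b = 0; b < B.size(); ++b) {
          int i = A[a], j = B[b];
          if (i < j) pairs.push_back(std::make_pair(i, j));
          else pairs.push_back(std::make_pair(j, i));
        }
    }
  }
  std::sort(pairs.begin(), pairs.end());
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairlist(NumericMatrix pos, NumericVector box, IntegerVector group_id,
                           double r_list, int scheme, bool use_cells) {
  std::vector<std::pair<int,int> > pairs;
  build_pairs(pos, box, group_id, r_list, scheme, use_cells, pairs);
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_group_centres(NumericMatrix pos, NumericVector box, IntegerVector group_id) {
  int n = pos.nrow(), ngrp = 0;
  for (int i = 0; i < n; ++i) ngrp = std::max(ngrp, group_id[i]);
  std::vector<double> cx, cy, cz;
  std::vector<std::vector<int> > members;
  group_centres(pos, group_id, box, ngrp, cx, cy, cz, members);
  NumericMatrix out(ngrp, 3);
  for (int g = 0; g < ngrp; ++g) { out(g,0)=cx[g]; out(g,1)=cy[g]; out(g,2)=cz[g]; }
  return out;
}

// ---------------------------------------------------------------------------
// tabulated pair potential (cubic Hermite on value + stored negative
// derivative, so the returned force is the exact gradient of the
// interpolated energy)
// ---------------------------------------------------------------------------

struct Table {
  const double *Vf, *Ff, *Vg, *Fg, *Vh, *Fh; // value and -derivative columns
  double r0, dr, rc_elec, rc_lj;
  int n;
};

static inline void herm(const double* V, const double* Fm, int i, double t, double dr,
                        double& v, double& dv) {
  double d0 = -Fm[i], d1 = -Fm[i + 1];  // dV/dr at the bracketing nodes
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2*t3 - 3*t2 + 1, h10 = t3 - 2*t2 + t, h01 = -2*t3 + 3*t2, h11 = t3 - t2;
  v = h00 * V[i] + h10 * dr * d0 + h01 * V[i+1] + h11 * dr * d1;
  double g00 = 6*t2 - 6*t, g10 = 3*t2 - 4*t + 1, g01 = -6*t2 + 6*t, g11 = 3*t2 - 2*t;
  dv = (g00 * V[i] + g10 * dr * d0 + g01 * V[i+1] + g11 * dr * d1) / dr;
}

// energy/force of one pair from the table; qq is the charge product,
// c6/c12 the combined LJ coefficients. Electrostatics clamp to exactly zero
// beyond rc_elec and LJ beyond rc_lj (this is what makes the pseudo cut-off
// construction identical to atom-based truncation).
static inline int tab_pair(const Table& T, double r, double qq, double c6, double c12,
                           double coul, double& e_el, double& e_lj, double& fr) {
  if (r < T.r0) return 1; // overlap: below table start
  int i = (int)((r - T.r0) / T.dr);
  if (i > T.n - 2) i = T.n - 2;
  double t = (r - (T.r0 + i * T.dr)) / T.dr;
  e_el = 0.0; e_lj = 0.0; fr = 0.0;
  if (qq != 0.0 && r <= T.rc_elec) {
    double v, dv; herm(T.Vf, T.Ff, i, t, T.dr, v, dv);
    e_el = coul * qq * v;
    fr += -coul * qq * dv;
  }
  if ((c6 != 0.0 || c12 != 0.0) && r <= T.rc_lj) {
    double vg, dvg, vh, dvh;
    herm(T.Vg, T.Fg, i, t, T.dr, vg, dvg);
    herm(T.Vh, T.Fh, i, t, T.dr, vh, dvh);
    e_lj = c6 * vg + c12 * vh;
    fr += -(c6 * dvg + c12 * dvh);
  }
  return 0;
}

static Table unpack_table(const List& tab) {
  Table T;
  NumericVector Vf = tab["Vf"], Ff = tab["Ff"], Vg = tab["Vg"], Fg = tab["Fg"],
                Vh = tab["Vh"], Fh = tab["Fh"];
  T.Vf = REAL(Vf); T.Ff = REAL(Ff); T.Vg = REAL(Vg); T.Fg = REAL(Fg);
  T.Vh = REAL(Vh); T.Fh = REAL(Fh);
  T.r0 = as<double>(tab["r0"]); T.dr = as<double>(tab["dr"]);
  T.rc_elec = as<double>(tab["rc_elec"]); T.rc_lj = as<double>(tab["rc_lj"]);
  T.n = Vf.size();
  return T;
}

// [[Rcpp::export]]
List cpp_nonbonded(NumericMatrix pos, NumericVector box, IntegerMatrix pairs,
                   NumericVector charge, NumericVector c6, NumericVector c12,
                   List tab, double coul) {
  Table T = unpack_table(tab);
  int n = pos.nrow();
  NumericMatrix force(n, 3);
  double E_el = 0.0, E_lj = 0.0;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double dx = min_image(pos(j,0) - pos(i,0), box[0]);
    double dy = min_image(pos(j,1) - pos(i,1), box[1]);
    double dz = min_image(pos(j,2) - pos(i,2), box[2]);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double qq = charge[i] * charge[j];
    double cc6 = std::sqrt(c6[i] * c6[j]), cc12 = std::sqrt(c12[i] * c12[j]);
    double eel, elj, fr;
    if (tab_pair(T, r, qq, cc6, cc12, coul, eel, elj, fr))
      stop("pair distance %f nm below table start %f nm (atomic overlap)", r, T.r0);
    E_el += eel; E_lj += elj;
    double s = fr / r;             // scalar force / r, along r_ij
    force(i,0) -= s * dx; force(i,1) -= s * dy; force(i,2) -= s * dz;
    force(j,0) += s * dx; force(j,1) += s * dy; force(j,2) += s * dz;
  }
  return List::create(_["e_elec"] = E_el, _["e_lj"] = E_lj, _["forces"] = force);
}

// ---------------------------------------------------------------------------
// direct Ewald summation (tin-foil boundary, intramolecular exclusions)
// ---------------------------------------------------------------------------

static const double TWO_OVER_SQRTPI = 1.1283791670955126;

static void ewald_compute(const NumericMatrix& pos, const NumericVector& box,
                          const NumericVector& charge, const IntegerVector& mol_id,
                          double alpha, double rcut, int kmax, double coul,
                          double& e_real, double& e_recip, double& e_self,
                          double& e_excl, NumericMatrix& force) {
  int n = pos.nrow();
  double rc2 = rcut * rcut;
  e_real = 0.0; e_recip = 0.0; e_self = 0.0; e_excl = 0.0;
  std::fill(force.begin(), force.end(), 0.0);

  // real space + intramolecular exclusion corrections
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(j,0) - pos(i,0), box[0]);
      double dy = min_image(pos(j,1) - pos(i,1), box[1]);
      double dz = min_image(pos(j,2) - pos(i,2), box[2]);
      double r2 = dx*dx + dy*dy + dz*dz;
      double qq = charge[i] * charge[j];
      if (qq == 0.0) continue;
      bool same_mol = (mol_id[i] == mol_id[j]);
      if (!same_mol) {
        if (r2 > rc2) continue;
        double r = std::sqrt(r2);
        double er = std::erfc(alpha * r);
        double e = coul * qq * er / r;
        e_real += e;
        double fr = coul * qq * (er / r2 + TWO_OVER_SQRTPI * alpha *
                                 std::exp(-alpha*alpha*r2) / r);
        double s = fr / r;
        force(i,0) -= s * dx; force(i,1) -= s * dy; force(i,2) -= s * dz;
        force(j,0) += s * dx; force(j,1) += s * dy; force(j,2) += s * dz;
      } else {
        // subtract the reciprocal-space (erf) part of the excluded pair
        double r = std::sqrt(r2);
        double ef = std::erf(alpha * r) / r;
        e_excl -= coul * qq * ef;
        // d/dr [erf(ar)/r] = 2a/sqrt(pi) exp(-a^2 r^2)/r - erf(ar)/r^2
        double dfdr = TWO_OVER_SQRTPI * alpha * std::exp(-alpha*alpha*r2) / r - ef / r;
        double fr = coul * qq * dfdr; // = -d(e_excl_pair)/dr
        double s = fr / r;
        force(i,0) -= s * dx; force(i,1) -= s * dy; force(i,2) -= s * dz;
        force(j,0) += s * dx; force(j,1) += s * dy; force(j,2) += s * dz;
      }
    }
  }

  // reciprocal space, spherical shell |n| <= kmax, half-space with factor 2
  double V = box[0] * box[1] * box[2];
  double pref = coul * 2.0 * M_PI / V;
  // per-dimension complex exponentials e^{i 2 pi m x / L}, m = 0..kmax
  std::vector<double> cx((kmax+1)*n), sx((kmax+1)*n), cy((kmax+1)*n), sy((kmax+1)*n),
                      cz((kmax+1)*n), sz((kmax+1)*n);
  for (int i = 0; i < n; ++i) {
    cx[i] = 1.0; sx[i] = 0.0; cy[i] = 1.0; sy[i] = 0.0; cz[i] = 1.0; sz[i] = 0.0;
    double ax = 2.0 * M_PI * pos(i,0) / box[0];
    double ay = 2.0 * M_PI * pos(i,1) / box[1];
    double az = 2.0 * M_PI * pos(i,2) / box[2];
    double c1x = std::cos(ax), s1x = std::sin(ax);
    double c1y = std::cos(ay), s1y = std::sin(ay);
    double c1z = std::cos(az), s1z = std::sin(az);
    for (int m = 1; m <= kmax; ++m) {
      cx[m*n+i] = cx[(m-1)*n+i]*c1x - sx[(m-1)*n+i]*s1x;
      sx[m*n+i] = sx[(m-1)*n+i]*c1x + cx[(m-1)*n+i]*s1x;
      cy[m*n+i] = cy[(m-1)*n+i]*c1y - sy[(m-1)*n+i]*s1y;
      sy[m*n+i] = sy[(m-1)*n+i]*c1y + cy[(m-1)*n+i]*s1y;
      cz[m*n+i] = cz[(m-1)*n+i]*c1z - sz[(m-1)*n+i]*s1z;
      sz[m*n+i] = sz[(m-1)*n+i]*c1z + cz[(m-1)*n+i]*s1z;
    }
  }
  std::vector<double> cfac(n), sfac(n);
  int k2max = kmax * kmax;
  for (int mx = 0; mx <= kmax; ++mx) {
    for (int my = (mx == 0 ? 0 : -kmax); my <= kmax; ++my) {
      for (int mz = ((mx == 0 && my == 0) ? 1 : -kmax); mz <= kmax; ++mz) {
        int m2 = mx*mx + my*my + mz*mz;
        if (m2 > k2max) continue;
        double kxv = 2.0 * M_PI * mx / box[0];
        double kyv = 2.0 * M_PI * my / box[1];
        double kzv = 2.0 * M_PI * mz / box[2];
        double k2 = kxv*kxv + kyv*kyv + kzv*kzv;
        double Ak = std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
        int amy = std::abs(my), amz = std::abs(mz);
        double Sre = 0.0, Sim = 0.0;
        for (int i = 0; i < n; ++i) {
          double cyi = cy[amy*n+i], syi = (my < 0 ? -sy[amy*n+i] : sy[amy*n+i]);
          double czi = cz[amz*n+i], szi = (mz < 0 ? -sz[amz*n+i] : sz[amz*n+i]);
          double cxy = cx[mx*n+i]*cyi - sx[mx*n+i]*syi;
          double sxy = sx[mx*n+i]*cyi + cx[mx*n+i]*syi;
          double cr = cxy*czi - sxy*szi;
          double sr = sxy*czi + cxy*szi;
          cfac[i] = cr; sfac[i] = sr;
          Sre += charge[i] * cr;
          Sim += charge[i] * sr;
        }
        double w = 2.0; // half-space
        e_recip += pref * w * Ak * (Sre*Sre + Sim*Sim);
        double fpref = 2.0 * pref * w * Ak;
        for (int i = 0; i < n; ++i) {
          double fs = fpref * charge[i] * (sfac[i] * Sre - cfac[i] * Sim);
          force(i,0) += fs * kxv; force(i,1) += fs * kyv; force(i,2) += fs * kzv;
        }
      }
    }
  }

  double q2 = 0.0;
  for (int i = 0; i < n; ++i) q2 += charge[i] * charge[i];
  e_self = -coul * alpha / std::sqrt(M_PI) * q2;
}

// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector box, NumericVector charge,
               IntegerVector mol_id, double alpha, double rcut, int kmax, double coul) {
  int n = pos.nrow();
  NumericMatrix force(n, 3);
  double er, ek, es, ex;
  ewald_compute(pos, box, charge, mol_id, alpha, rcut, kmax, coul, er, ek, es, ex, force);
  return List::create(_["e_real"] = er, _["e_recip"] = ek, _["e_self"] = es,
                      _["e_excl"] = ex, _["energy"] = er + ek + es + ex,
                      _["forces"] = force);
}

// ---------------------------------------------------------------------------
// SHAKE / RATTLE
// ---------------------------------------------------------------------------

// Iterative SHAKE: corrects `newpos` so that every constraint distance d0 is
// met within rel_tol, using constraint directions from `refpos`.
// Returns iteration count, or -1 on non-convergence.
static int shake_correct(const NumericMatrix& refpos, NumericMatrix& newpos,
                         const IntegerMatrix& cons, const NumericVector& d0,
                         const NumericVector& invmass, const NumericVector& box,
                         double rel_tol, int maxit) {
  int nc = cons.nrow();
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int c = 0; c < nc; ++c) {
      int i = cons(c,0) - 1, j = cons(c,1) - 1;
      double dx = min_image(newpos(j,0) - newpos(i,0), box[0]);
      double dy = min_image(newpos(j,1) - newpos(i,1), box[1]);
      double dz = min_image(newpos(j,2) - newpos(i,2), box[2]);
      double d2 = dx*dx + dy*dy + dz*dz;
      double diff = d2 - d0[c]*d0[c];
      if (std::fabs(diff) > 2.0 * rel_tol * d0[c]*d0[c]) {
        done = false;
        double rx = min_image(refpos(j,0) - refpos(i,0), box[0]);
        double ry = min_image(refpos(j,1) - refpos(i,1), box[1]);
        double rz = min_image(refpos(j,2) - refpos(i,2), box[2]);
        double dot = rx*dx + ry*dy + rz*dz;
        double g = diff / (2.0 * (invmass[i] + invmass[j]) * dot);
        newpos(i,0) += g * invmass[i] * rx;
        newpos(i,1) += g * invmass[i] * ry;
        newpos(i,2) += g * invmass[i] * rz;
        newpos(j,0) -= g * invmass[j] * rx;
        newpos(j,1) -= g * invmass[j] * ry;
        newpos(j,2) -= g * invmass[j] * rz;
      }
    }
    if (done) return it;
  }
  return -1;
}

// RATTLE velocity stage: remove relative velocity components along constraints.
static int rattle_correct(const NumericMatrix& pos, NumericMatrix& vel,
                          const IntegerMatrix& cons, const NumericVector& d0,
                          const NumericVector& invmass, const NumericVector& box,
                          double tol, int maxit) {
  int nc = cons.nrow();
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int c = 0; c < nc; ++c) {
      int i = cons(c,0) - 1, j = cons(c,1) - 1;
      double rx = min_image(pos(j,0) - pos(i,0), box[0]);
      double ry = min_image(pos(j,1) - pos(i,1), box[1]);
      double rz = min_image(pos(j,2) - pos(i,2), box[2]);
      double vx = vel(j,0) - vel(i,0), vy = vel(j,1) - vel(i,1), vz = vel(j,2) - vel(i,2);
      double rv = rx*vx + ry*vy + rz*vz;
      double d2 = d0[c]*d0[c];
      if (std::fabs(rv) > tol * d2) {
        done = false;
        double g = rv / (d2 * (invmass[i] + invmass[j]));
        vel(i,0) += g * invmass[i] * rx;
        vel(i,1) += g * invmass[i] * ry;
        vel(i,2) += g * invmass[i] * rz;
        vel(j,0) -= g * invmass[j] * rx;
        vel(j,1) -= g * invmass[j] * ry;
        vel(j,2) -= g * invmass[j] * rz;
      }
    }
    if (done) return it;
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_shake(NumericMatrix refpos, NumericMatrix newpos, IntegerMatrix cons,
               NumericVector d0, NumericVector invmass, NumericVector box,
               double rel_tol, int maxit) {
  NumericMatrix corrected = clone(newpos);
  int it = shake_correct(refpos, corrected, cons, d0, invmass, box, rel_tol, maxit);
  if (it < 0) {
    // report the worst constraint
    int worst = 0; double wv = 0.0;
    for (int c = 0; c < cons.nrow(); ++c) {
      int i = cons(c,0) - 1, j = cons(c,1) - 1;
      double dx = min_image(corrected(j,0) - corrected(i,0), box[0]);
      double dy = min_image(corrected(j,1) - corrected(i,1), box[1]);
      double dz = min_image(corrected(j,2) - corrected(i,2), box[2]);
      double rel = std::fabs(std::sqrt(dx*dx+dy*dy+dz*dz) - d0[c]) / d0[c];
      if (rel > wv) { wv = rel; worst = c; }
    }
    stop("SHAKE failed to converge in %d iterations; worst constraint %d (relative error %g)",
         maxit, worst + 1, wv);
  }
  return List::create(_["positions"] = corrected, _["iterations"] = it);
}

// [[Rcpp::export]]
List cpp_rattle(NumericMatrix pos, NumericMatrix vel, IntegerMatrix cons,
                NumericVector d0, NumericVector invmass, NumericVector box,
                double tol, int maxit) {
  NumericMatrix v = clone(vel);
  int it = rattle_correct(pos, v, cons, d0, invmass, box, tol, maxit);
  if (it < 0) stop("RATTLE failed to converge in %d iterations", maxit);
  return List::create(_["velocities"] = v, _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// MD driver: velocity Verlet + SHAKE/RATTLE, optional single-chain
// Nose-Hoover thermostat, tabulated or Ewald force field
// ---------------------------------------------------------------------------

struct ForceField {
  int type;          // 0 = tabulated, 1 = ewald
  Table T;           // tabulated
  int scheme;        // 0 atom, 1 group (tabulated path)
  double r_list;
  double alpha, rcut; int kmax;   // ewald path
  double rc_lj;                    // ewald path LJ truncation (atom-based)
  double coul;
};

// per-run scratch for the tabulated force path
struct Workspace {
  int ngrp;
  std::vector<std::vector<int> > members;
  std::vector<double> cx, cy, cz;
  std::vector<double> sc6, sc12;   // per-atom sqrt(c6), sqrt(c12)
};

static void make_workspace(const NumericMatrix& pos, const IntegerVector& group_id,
                           const NumericVector& c6, const NumericVector& c12,
                           Workspace& W) {
  int n = pos.nrow();
  W.ngrp = 0;
  for (int i = 0; i < n; ++i) W.ngrp = std::max(W.ngrp, group_id[i]);
  W.members.assign(W.ngrp, std::vector<int>());
  for (int i = 0; i < n; ++i) W.members[group_id[i] - 1].push_back(i);
  W.sc6.resize(n); W.sc12.resize(n);
  for (int i = 0; i < n; ++i) {
    W.sc6[i] = std::sqrt(c6[i]);
    W.sc12[i] = std::sqrt(c12[i]);
  }
}

// centres using the workspace's prebuilt member lists (no reallocation)
static void group_centres_ws(const NumericMatrix& pos, const NumericVector& box,
                             Workspace& W) {
  int n3 = pos.nrow();
  const double* P = REAL(pos);
  W.cx.resize(W.ngrp); W.cy.resize(W.ngrp); W.cz.resize(W.ngrp);
  for (int g = 0; g < W.ngrp; ++g) {
    const std::vector<int>& mem = W.members[g];
    if (mem.empty()) { W.cx[g] = W.cy[g] = W.cz[g] = 0.0; continue; }
    int a0 = mem[0];
    double sx = 0, sy = 0, sz = 0;
    for (size_t k = 1; k < mem.size(); ++k) {
      int a = mem[k];
      sx += min_image(P[a] - P[a0], box[0]);
      sy += min_image(P[a + n3] - P[a0 + n3], box[1]);
      sz += min_image(P[a + 2 * n3] - P[a0 + 2 * n3], box[2]);
    }
    double m = (double)mem.size();
    W.cx[g] = P[a0] + sx / m;
    W.cy[g] = P[a0 + n3] + sy / m;
    W.cz[g] = P[a0 + 2 * n3] + sz / m;
  }
}

static inline int eval_add(const ForceField& ff, const double* P, int n,
                           const double* box, const double* charge,
                           const double* sc6, const double* sc12,
                           int i, int j, double& e_el, double& e_lj,
                           double* F) {
  double dx = min_image(P[j] - P[i], box[0]);
  double dy = min_image(P[j + n] - P[i + n], box[1]);
  double dz = min_image(P[j + 2 * n] - P[i + 2 * n], box[2]);
  double r = std::sqrt(dx*dx + dy*dy + dz*dz);
  double qq = charge[i] * charge[j];
  double cc6 = sc6[i] * sc6[j], cc12 = sc12[i] * sc12[j];
  double eel, elj, fr;
  if (tab_pair(ff.T, r, qq, cc6, cc12, ff.coul, eel, elj, fr))
    return 1;   // overlap below table start; reported by the caller
  e_el += eel; e_lj += elj;
  double s = fr / r;
  F[i] -= s * dx; F[i + n] -= s * dy; F[i + 2 * n] -= s * dz;
  F[j] += s * dx; F[j + n] += s * dy; F[j + 2 * n] += s * dz;
  return 0;
}

static void ff_energy_forces(const ForceField& ff, const NumericMatrix& pos,
                             const NumericVector& box, const NumericVector& charge,
                             const NumericVector& c6, const NumericVector& c12,
                             const IntegerVector& group_id, const IntegerVector& mol_id,
                             Workspace& W, double& e_el, double& e_lj,
                             NumericMatrix& force) {
  int n = pos.nrow();
  std::fill(force.begin(), force.end(), 0.0);
  e_el = 0.0; e_lj = 0.0;
  if (ff.type == 0) {
    double r2 = ff.r_list * ff.r_list;
    const double* P = REAL(pos);
    const double* bx = REAL(box);
    const double* q = REAL(charge);
    const double* a6 = W.sc6.data();
    const double* a12 = W.sc12.data();
    double* F = REAL(force);
    int bad = 0;
    if (ff.scheme == 1) {
      group_centres_ws(pos, box, W);
      for (int ga = 0; ga < W.ngrp - 1; ++ga)
        for (int gb = ga + 1; gb < W.ngrp; ++gb) {
          double dx = min_image(W.cx[gb] - W.cx[ga], box[0]);
          double dy = min_image(W.cy[gb] - W.cy[ga], box[1]);
          double dz = min_image(W.cz[gb] - W.cz[ga], box[2]);
          if (dx*dx + dy*dy + dz*dz > r2) continue;
          const std::vector<int>& A = W.members[ga];
          const std::vector<int>& B = W.members[gb];
          for (size_t a = 0; a < A.size(); ++a)
            for (size_t b = 0; b < B.size(); ++b)
              bad += eval_add(ff, P, n, bx, q, a6, a12, A[a], B[b], e_el, e_lj, F);
        }
    } else {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (group_id[i] == group_id[j]) continue;
          double dx = min_image(P[j] - P[i], box[0]);
          double dy = min_image(P[j + n] - P[i + n], box[1]);
          double dz = min_image(P[j + 2 * n] - P[i + 2 * n], box[2]);
          if (dx*dx + dy*dy + dz*dz > r2) continue;
          bad += eval_add(ff, P, n, bx, q, a6, a12, i, j, e_el, e_lj, F);
        }
    }
    if (bad > 0)
      stop("atomic overlap: %d pair(s) below the table start", bad);
  } else {
    double er, ek, es, ex;
    ewald_compute(pos, box, charge, mol_id, ff.alpha, ff.rcut, ff.kmax, ff.coul,
                  er, ek, es, ex, force);
    e_el = er + ek + es + ex;
    // atom-based plain-truncated LJ
    double rc2 = ff.rc_lj * ff.rc_lj;
    for (int i = 0; i < n - 1; ++i) {
      if (c6[i] == 0.0 && c12[i] == 0.0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (mol_id[i] == mol_id[j]) continue;
        if (c6[j] == 0.0 && c12[j] == 0.0) continue;
        double dx = min_image(pos(j,0) - pos(i,0), box[0]);
        double dy = min_image(pos(j,1) - pos(i,1), box[1]);
        double dz = min_image(pos(j,2) - pos(i,2), box[2]);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 > rc2) continue;
        double cc6 = std::sqrt(c6[i]*c6[j]), cc12 = std::sqrt(c12[i]*c12[j]);
        double ir2 = 1.0 / r2, ir6 = ir2*ir2*ir2;
        e_lj += (cc12 * ir6 - cc6) * ir6;
        double fr_r = (12.0 * cc12 * ir6 - 6.0 * cc6) * ir6 * ir2; // (-dE/dr)/r
        force(i,0) -= fr_r * dx; force(i,1) -= fr_r * dy; force(i,2) -= fr_r * dz;
        force(j,0) += fr_r * dx; force(j,1) += fr_r * dy; force(j,2) += fr_r * dz;
      }
    }
  }
}

static ForceField unpack_ff(const List& ff) {
  ForceField F;
  F.type = as<int>(ff["type"]);
  F.coul = as<double>(ff["coul"]);
  if (F.type == 0) {
    F.T = unpack_table(ff["table"]);
    F.scheme = as<int>(ff["scheme"]);
    F.r_list = as<double>(ff["r_list"]);
  } else {
    F.alpha = as<double>(ff["alpha"]);
    F.rcut = as<double>(ff["rcut"]);
    F.kmax = as<int>(ff["kmax"]);
    F.rc_lj = as<double>(ff["rc_lj"]);
  }
  return F;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box, NumericVector charge,
                       NumericVector c6, NumericVector c12, IntegerVector group_id,
                       IntegerVector mol_id, List ff) {
  ForceField F = unpack_ff(ff);
  NumericMatrix force(pos.nrow(), 3);
  Workspace W;
  make_workspace(pos, group_id, c6, c12, W);
  double eel, elj;
  ff_energy_forces(F, pos, box, charge, c6, c12, group_id, mol_id, W, eel, elj, force);
  return List::create(_["e_elec"] = eel, _["e_lj"] = elj, _["forces"] = force);
}

static inline double kinetic_energy(const NumericMatrix& vel, const NumericVector& mass) {
  double k = 0.0;
  for (int i = 0; i < vel.nrow(); ++i)
    k += mass[i] * (vel(i,0)*vel(i,0) + vel(i,1)*vel(i,1) + vel(i,2)*vel(i,2));
  return 0.5 * k;
}

// Single-chain Nose-Hoover half operator over time h:
// xi += h/2 G; scale v by exp(-xi h); xi += h/2 G' (G recomputed).
static void nh_half(NumericMatrix& vel, const NumericVector& mass, double& xi,
                    double h, double Q, double nf_kT) {
  double K = kinetic_energy(vel, mass);
  double G = (2.0 * K - nf_kT) / Q;
  xi += 0.5 * h * G;
  double s = std::exp(-xi * h);
  for (int i = 0; i < vel.nrow(); ++i) {
    vel(i,0) *= s; vel(i,1) *= s; vel(i,2) *= s;
  }
  K *= s * s;
  G = (2.0 * K - nf_kT) / Q;
  xi += 0.5 * h * G;
}

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector box,
                NumericVector mass, NumericVector charge, NumericVector c6,
                NumericVector c12, IntegerVector group_id, IntegerVector mol_id,
                IntegerMatrix cons, NumericVector d0, List ff, double dt,
                int n_steps, int stride, bool nvt, double T_target, double tau,
                double ndof, double shake_tol, double kB) {
  int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix force(n, 3), ref(n, 3);
  NumericVector invmass(n);
  for (int i = 0; i < n; ++i) invmass[i] = 1.0 / mass[i];
  ForceField F = unpack_ff(ff);
  bool have_cons = cons.nrow() > 0;
  std::vector<double> unconstrained(3 * n);
  Workspace W;
  make_workspace(pos, group_id, c6, c12, W);
  double xi = 0.0;
  double nf_kT = ndof * kB * T_target;
  double Q = nf_kT * tau * tau;
  int maxit = 500;

  int n_frames = n_steps / stride + 1;
  NumericVector frames(n_frames * n * 3);
  NumericVector tr_time(n_steps + 1), tr_eel(n_steps + 1), tr_elj(n_steps + 1),
                tr_kin(n_steps + 1), tr_xi(n_steps + 1);
  NumericMatrix tr_mom(n_steps + 1, 3);

  double eel, elj;
  ff_energy_forces(F, pos, box, charge, c6, c12, group_id, mol_id, W, eel, elj, force);

  int fidx = 0;
  for (int step = 0; step <= n_steps; ++step) {
    // record
    tr_time[step] = step * dt;
    tr_eel[step] = eel; tr_elj[step] = elj;
    tr_kin[step] = kinetic_energy(vel, mass);
    tr_xi[step] = xi;
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < n; ++i) {
      px += mass[i]*vel(i,0); py += mass[i]*vel(i,1); pz += mass[i]*vel(i,2);
    }
    tr_mom(step,0) = px; tr_mom(step,1) = py; tr_mom(step,2) = pz;
    if (step % stride == 0 && fidx < n_frames) {
      for (int i = 0; i < n; ++i) {
        frames[fidx * n * 3 + i] = pos(i,0);
        frames[fidx * n * 3 + n + i] = pos(i,1);
        frames[fidx * n * 3 + 2 * n + i] = pos(i,2);
      }
      ++fidx;
    }
    if (step == n_steps) break;
    if (tr_kin[step] > 1e7 || !std::isfinite(tr_kin[step]))
      stop("simulation blew up at step %d (kinetic energy %g kJ/mol)", step, tr_kin[step]);

    if (nvt) nh_half(vel, mass, xi, 0.5 * dt, Q, nf_kT);

    // half kick
    for (int i = 0; i < n; ++i) {
      vel(i,0) += 0.5 * dt * force(i,0) * invmass[i];
      vel(i,1) += 0.5 * dt * force(i,1) * invmass[i];
      vel(i,2) += 0.5 * dt * force(i,2) * invmass[i];
    }
    // drift + SHAKE
    for (int i = 0; i < n; ++i) {
      ref(i,0) = pos(i,0); ref(i,1) = pos(i,1); ref(i,2) = pos(i,2);
      pos(i,0) += dt * vel(i,0); pos(i,1) += dt * vel(i,1); pos(i,2) += dt * vel(i,2);
    }
    if (have_cons) {
      std::copy(pos.begin(), pos.end(), unconstrained.begin());
      int it = shake_correct(ref, pos, cons, d0, invmass, box, shake_tol, maxit);
      if (it < 0) stop("SHAKE failed to converge at step %d", step);
      // velocity update from the position correction
      for (int i = 0; i < n; ++i) {
        vel(i,0) += (pos(i,0) - unconstrained[i]) / dt;
        vel(i,1) += (pos(i,1) - unconstrained[i + n]) / dt;
        vel(i,2) += (pos(i,2) - unconstrained[i + 2 * n]) / dt;
      }
    }
    // forces at new positions, second half kick
    ff_energy_forces(F, pos, box, charge, c6, c12, group_id, mol_id, W, eel, elj, force);
    for (int i = 0; i < n; ++i) {
      vel(i,0) += 0.5 * dt * force(i,0) * invmass[i];
      vel(i,1) += 0.5 * dt * force(i,1) * invmass[i];
      vel(i,2) += 0.5 * dt * force(i,2) * invmass[i];
    }
    if (have_cons) {
      int it = rattle_correct(pos, vel, cons, d0, invmass, box, 1e-10, maxit);
      if (it < 0) stop("RATTLE failed to converge at step %d", step);
    }
    if (nvt) nh_half(vel, mass, xi, 0.5 * dt, Q, nf_kT);
  }

  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(_["frames"] = frames, _["positions"] = pos, _["velocities"] = vel,
                      _["time"] = tr_time, _["e_elec"] = tr_eel, _["e_lj"] = tr_elj,
                      _["kinetic"] = tr_kin, _["xi"] = tr_xi, _["momentum"] = tr_mom);
}

// ---------------------------------------------------------------------------
// binned pair statistics for the observables
// ---------------------------------------------------------------------------

// Histogram of pair distances (each unordered pair once) and, when dipoles
// are supplied, the per-bin sum of u_i . u_j and the shell-wise per-molecule
// mean of u_i . u_j summed over molecules (for <cos theta(r)>).
// [[Rcpp::export]]
List cpp_pair_bins(NumericMatrix pos, NumericMatrix dip, NumericVector box,
                   double dr, int nbins, bool with_dipoles) {
  int n = pos.nrow();
  NumericVector counts(nbins), dots(nbins), coshell(nbins);
  std::vector<double> icnt, idot;
  if (with_dipoles) { icnt.assign((size_t)n * nbins, 0.0); idot.assign((size_t)n * nbins, 0.0); }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(j,0) - pos(i,0), box[0]);
      double dy = min_image(pos(j,1) - pos(i,1), box[1]);
      double dz = min_image(pos(j,2) - pos(i,2), box[2]);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      int b = (int)(r / dr);
      if (b >= nbins) continue;
      counts[b] += 1.0;
      if (with_dipoles) {
        double u = dip(i,0)*dip(j,0) + dip(i,1)*dip(j,1) + dip(i,2)*dip(j,2);
        dots[b] += u;
        icnt[(size_t)i * nbins + b] += 1.0; icnt[(size_t)j * nbins + b] += 1.0;
        idot[(size_t)i * nbins + b] += u;   idot[(size_t)j * nbins + b] += u;
      }
    }
  }
  if (with_dipoles) {
    for (int i = 0; i < n; ++i)
      for (int b = 0; b < nbins; ++b) {
        double c = icnt[(size_t)i * nbins + b];
        if (c > 0) coshell[b] += idot[(size_t)i * nbins + b] / c;
      }
  }
  return List::create(_["counts"] = counts, _["dots"] = dots, _["coshell"] = coshell);
}

// Unwrap a trajectory (natoms x 3 x nframes array) by accumulating per-frame
// minimum-image displacements; required before computing MSDs.
// [[Rcpp::export]]
NumericVector cpp_unwrap_arr(NumericVector frames, NumericVector box) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  NumericVector out(clone(frames));
  for (int f = 1; f < nf; ++f)
    for (int d = 0; d < 3; ++d)
      for (int i = 0; i < n; ++i) {
        size_t cur = (size_t)f * n * 3 + (size_t)d * n + i;
        size_t prev = (size_t)(f-1) * n * 3 + (size_t)d * n + i;
        double step = min_image(frames[cur] - frames[prev], box[d]);
        out[cur] = out[prev] + step;
      }
  out.attr("dim") = dim;
  return out;
}
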