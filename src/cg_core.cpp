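// Coarse-grained force field (Calpha protein + three-bead DNA) and
// BAOAB Langevin integrator.  Units: nm, kJ/mol, ps, amu, e.
//
// Terms: harmonic bonds/angles, cosine dihedrals, Debye-Hueckel screened
// Coulomb (shifted at 4 lambda_D), specific pair lists (12-10-6 native
// and 12-6 stack/pair), and generic class-based 12-6 nonbonded terms
// (shifted at their cutoff) with 1-2/1-3/1-4 and pair-list exclusions.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

static const double KE_COUL = 138.935458; // kJ mol^-1 nm e^-2

struct FF {
  int n;
  double box; // <= 0 -> non-periodic
  std::vector<double> charge, mass;
  std::vector<int> cls;
  // bonds
  std::vector<int> b_i, b_j; std::vector<double> b_k, b_d0;
  // angles
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_kt, a_t0;
  // dihedral terms (one row per cosine term)
  std::vector<int> d_i, d_j, d_k, d_l, d_n;
  std::vector<double> d_km, d_del;
  // specific pairs
  std::vector<int> p_i, p_j, p_form; std::vector<double> p_eps, p_sig;
  // generic class table (nc x nc)
  int ncls;
  std::vector<double> tab_eps, tab_sig;
  // exclusions (sorted keys i*n+j, i<j)
  std::vector<double> excl_bonded, excl_pair;
  // electrostatics
  double eps_d, lambda_D, rc_e, rc_lj, skin;
  // neighbour lists with precomputed per-pair parameters
  std::vector<int> nb_lj_i, nb_lj_j, nb_e_i, nb_e_j;
  std::vector<double> lj_eps4, lj_sig2, lj_rc2, lj_vshift;
  std::vector<double> e_pref, e_vshift;
  std::vector<double> ref_x; // coords at last rebuild
  bool has_list = false;

  inline bool excluded(const std::vector<double>& set, int i, int j) const {
    double key = (double)std::min(i, j) * n + std::max(i, j);
    return std::binary_search(set.begin(), set.end(), key);
  }
  inline void mind(double& dx, double& dy, double& dz) const {
    if (box > 0) {
      dx -= box * std::nearbyint(dx / box);
      dy -= box * std::nearbyint(dy / box);
      dz -= box * std::nearbyint(dz / box);
    }
  }

  void add_pair(const std::vector<double>& x, int i, int j,
                double rlj2, double re2) {
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
           dz = x[3*i+2] - x[3*j+2];
    mind(dx, dy, dz);
    double d2 = dx*dx + dy*dy + dz*dz;
    bool want_lj = d2 < rlj2;
    bool want_e = charge[i] != 0 && charge[j] != 0 && d2 < re2;
    if (!want_lj && !want_e) return;
    if (excluded(excl_bonded, i, j)) return;
    if (want_lj && !excluded(excl_pair, i, j)) {
      double eps = tab_eps[cls[i]*ncls + cls[j]];
      if (eps != 0) {
        double sig = tab_sig[cls[i]*ncls + cls[j]];
        double rc = std::min(rc_lj, 2.5 * sig);
        double rlist = rc + skin;
        if (d2 >= rlist * rlist) { if (!want_e) return; goto elec_part; }
        double sc2 = sig*sig/(rc*rc), sc6 = sc2*sc2*sc2;
        nb_lj_i.push_back(i); nb_lj_j.push_back(j);
        lj_eps4.push_back(4.0*eps); lj_sig2.push_back(sig*sig);
        lj_rc2.push_back(rc*rc);
        lj_vshift.push_back(4.0*eps*(sc6*sc6 - sc6));
      }
    }
    elec_part:
    if (want_e) {
      double pref = KE_COUL / eps_d * charge[i] * charge[j];
      nb_e_i.push_back(i); nb_e_j.push_back(j);
      e_pref.push_back(pref);
      e_vshift.push_back(pref / rc_e * std::exp(-rc_e / lambda_D));
    }
  }

  // cell-list neighbour search over the coordinate bounding box
  void build_list(const std::vector<double>& x) {
    nb_lj_i.clear(); nb_lj_j.clear(); nb_e_i.clear(); nb_e_j.clear();
    lj_eps4.clear(); lj_sig2.clear(); lj_rc2.clear(); lj_vshift.clear();
    e_pref.clear(); e_vshift.clear();
    const double rlj = rc_lj + skin, re = rc_e + skin;
    const double rlj2 = rlj * rlj, re2 = re * re;
    const double rmax = std::max(rlj, re);
    // periodic systems spanning the box fall back to the O(n^2) scan;
    // cell lists apply when the system is compact (typical here)
    double lo[3] = {x[0], x[1], x[2]}, hi[3] = {x[0], x[1], x[2]};
    for (int i = 1; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], x[3*i+k]);
        hi[k] = std::max(hi[k], x[3*i+k]);
      }
    bool compact = box <= 0 ||
      (hi[0]-lo[0] < box - rmax && hi[1]-lo[1] < box - rmax &&
       hi[2]-lo[2] < box - rmax);
    if (!compact) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          add_pair(x, i, j, rlj2, re2);
    } else {
      int nc[3]; double orig[3];
      long ncell = 1;
      for (int k = 0; k < 3; ++k) {
        orig[k] = lo[k];
        nc[k] = std::max(1, (int)((hi[k] - lo[k]) / rmax));
        ncell *= nc[k];
      }
      std::vector<std::vector<int>> cells(ncell);
      std::vector<int> ci(n);
      for (int i = 0; i < n; ++i) {
        int cx = std::min(nc[0]-1, (int)((x[3*i]   - orig[0]) / rmax));
        int cy = std::min(nc[1]-1, (int)((x[3*i+1] - orig[1]) / rmax));
        int cz = std::min(nc[2]-1, (int)((x[3*i+2] - orig[2]) / rmax));
        ci[i] = (cx * nc[1] + cy) * nc[2] + cz;
        cells[ci[i]].push_back(i);
      }
      for (int cx = 0; cx < nc[0]; ++cx)
      for (int cy = 0; cy < nc[1]; ++cy)
      for (int cz = 0; cz < nc[2]; ++cz) {
        int c1 = (cx * nc[1] + cy) * nc[2] + cz;
        const std::vector<int>& l1 = cells[c1];
        if (l1.empty()) continue;
        for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int nx = cx+ox, ny = cy+oy, nz = cz+oz;
          if (nx < 0 || ny < 0 || nz < 0 ||
              nx >= nc[0] || ny >= nc[1] || nz >= nc[2]) continue;
          int c2 = (nx * nc[1] + ny) * nc[2] + nz;
          if (c2 < c1) continue;
          const std::vector<int>& l2 = cells[c2];
          for (size_t a = 0; a < l1.size(); ++a) {
            size_t b0 = (c1 == c2) ? a + 1 : 0;
            for (size_t b = b0; b < l2.size(); ++b) {
              int i = l1[a], j = l2[b];
              if (i > j) std::swap(i, j);
              add_pair(x, i, j, rlj2, re2);
            }
          }
        }
      }
    }
    ref_x = x;
    has_list = true;
  }

  bool need_rebuild(const std::vector<double>& x) const {
    if (!has_list) return true;
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[3*i] - ref_x[3*i], dy = x[3*i+1] - ref_x[3*i+1],
             dz = x[3*i+2] - ref_x[3*i+2];
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }

  // Returns total energy; accumulates forces; fills term breakdown.
  double compute(const std::vector<double>& x, std::vector<double>& f,
                 double* terms /* 6: bond, angle, dih, elec, native, lj */) {
    if (need_rebuild(x)) build_list(x);
    std::fill(f.begin(), f.end(), 0.0);
    for (int t = 0; t < 6; ++t) terms[t] = 0.0;

    // bonds
    for (size_t b = 0; b < b_i.size(); ++b) {
      int i = b_i[b], j = b_j[b];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      mind(dx, dy, dz);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dev = d - b_d0[b];
      terms[0] += 0.5 * b_k[b] * dev * dev;
      double fac = -b_k[b] * dev / std::max(d, 1e-12);
      f[3*i] += fac*dx; f[3*i+1] += fac*dy; f[3*i+2] += fac*dz;
      f[3*j] -= fac*dx; f[3*j+1] -= fac*dy; f[3*j+2] -= fac*dz;
    }

    // angles
    for (size_t a = 0; a < a_i.size(); ++a) {
      int i = a_i[a], j = a_j[a], k = a_k[a];
      double ax = x[3*i]-x[3*j], ay = x[3*i+1]-x[3*j+1], az = x[3*i+2]-x[3*j+2];
      double bx = x[3*k]-x[3*j], by = x[3*k+1]-x[3*j+1], bz = x[3*k+2]-x[3*j+2];
      mind(ax, ay, az); mind(bx, by, bz);
      double la = std::sqrt(ax*ax+ay*ay+az*az), lb = std::sqrt(bx*bx+by*by+bz*bz);
      double ct = (ax*bx+ay*by+az*bz) / (la*lb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct), st = std::sqrt(std::max(1.0 - ct*ct, 1e-12));
      double dev = th - a_t0[a];
      terms[1] += 0.5 * a_kt[a] * dev * dev;
      double dVdt = a_kt[a] * dev;
      double ux = ax/la, uy = ay/la, uz = az/la;
      double vx = bx/lb, vy = by/lb, vz = bz/lb;
      double fi_x = dVdt * (vx - ct*ux) / (la * st);
      double fi_y = dVdt * (vy - ct*uy) / (la * st);
      double fi_z = dVdt * (vz - ct*uz) / (la * st);
      double fk_x = dVdt * (ux - ct*vx) / (lb * st);
      double fk_y = dVdt * (uy - ct*vy) / (lb * st);
      double fk_z = dVdt * (uz - ct*vz) / (lb * st);
      f[3*i] += fi_x; f[3*i+1] += fi_y; f[3*i+2] += fi_z;
      f[3*k] += fk_x; f[3*k+1] += fk_y; f[3*k+2] += fk_z;
      f[3*j] -= fi_x + fk_x; f[3*j+1] -= fi_y + fk_y; f[3*j+2] -= fi_z + fk_z;
    }

    // dihedrals
    for (size_t d = 0; d < d_i.size(); ++d) {
      int i = d_i[d], j = d_j[d], k = d_k[d], l = d_l[d];
      double b1x = x[3*j]-x[3*i], b1y = x[3*j+1]-x[3*i+1], b1z = x[3*j+2]-x[3*i+2];
      double b2x = x[3*k]-x[3*j], b2y = x[3*k+1]-x[3*j+1], b2z = x[3*k+2]-x[3*j+2];
      double b3x = x[3*l]-x[3*k], b3y = x[3*l+1]-x[3*k+1], b3z = x[3*l+2]-x[3*k+2];
      mind(b1x, b1y, b1z); mind(b2x, b2y, b2z); mind(b3x, b3y, b3z);
      double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z,
             n1z = b1x*b2y - b1y*b2x;
      double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z,
             n2z = b2x*b3y - b2y*b3x;
      double lb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
      double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
      double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
      // skip near-collinear quadruples: phi is ill-defined and the
      // force diverges as 1/sin(theta); the torsional energy there is
      // bounded by 2k per term
      double b1sq = b1x*b1x + b1y*b1y + b1z*b1z;
      double lim = 1e-6 * lb2 * lb2;
      if (n1sq < lim * b1sq ||
          n2sq < lim * (b3x*b3x + b3y*b3y + b3z*b3z)) continue;
      double cx = n1y*n2z - n1z*n2y, cy = n1z*n2x - n1x*n2z,
             cz = n1x*n2y - n1y*n2x;
      double sinp = (cx*b2x + cy*b2y + cz*b2z) / lb2;
      double cosp = n1x*n2x + n1y*n2y + n1z*n2z;
      double phi = std::atan2(sinp, cosp);
      int mult = d_n[d];
      terms[2] += d_km[d] * (1.0 + std::cos(mult*phi - d_del[d]));
      double dVdphi = -d_km[d] * mult * std::sin(mult*phi - d_del[d]);
      // gradient of phi w.r.t. the four bead positions
      double gix = -lb2 / n1sq * n1x, giy = -lb2 / n1sq * n1y,
             giz = -lb2 / n1sq * n1z;
      double glx =  lb2 / n2sq * n2x, gly =  lb2 / n2sq * n2y,
             glz =  lb2 / n2sq * n2z;
      double t1 = (b1x*b2x + b1y*b2y + b1z*b2z) / (lb2*lb2);
      double t2 = (b3x*b2x + b3y*b2y + b3z*b2z) / (lb2*lb2);
      double gjx = -(1+t1)*gix + t2*glx;
      double gjy = -(1+t1)*giy + t2*gly;
      double gjz = -(1+t1)*giz + t2*glz;
      double gkx = t1*gix - (1+t2)*glx;
      double gky = t1*giy - (1+t2)*gly;
      double gkz = t1*giz - (1+t2)*glz;
      f[3*i] -= dVdphi*gix; f[3*i+1] -= dVdphi*giy; f[3*i+2] -= dVdphi*giz;
      f[3*j] -= dVdphi*gjx; f[3*j+1] -= dVdphi*gjy; f[3*j+2] -= dVdphi*gjz;
      f[3*k] -= dVdphi*gkx; f[3*k+1] -= dVdphi*gky; f[3*k+2] -= dVdphi*gkz;
      f[3*l] -= dVdphi*glx; f[3*l+1] -= dVdphi*gly; f[3*l+2] -= dVdphi*glz;
    }

    // specific pairs (no cutoff)
    for (size_t p = 0; p < p_i.size(); ++p) {
      int i = p_i[p], j = p_j[p];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      mind(dx, dy, dz);
      double d2 = dx*dx + dy*dy + dz*dz;
      double d = std::sqrt(d2);
      if (d < 1e-6) stop("overlapping beads in specific pair list");
      double s2 = p_sig[p]*p_sig[p] / d2;
      double s6 = s2*s2*s2;
      double V, dVdd;
      if (p_form[p] == 1) { // 12-10-6 native
        double s10 = s6*s2*s2, s12 = s6*s6;
        V = p_eps[p] * (13.0*s12 - 18.0*s10 + 4.0*s6);
        dVdd = p_eps[p] * (-156.0*s12 + 180.0*s10 - 24.0*s6) / d;
        terms[4] += V;
      } else {              // 12-6
        double s12 = s6*s6;
        V = 4.0 * p_eps[p] * (s12 - s6);
        dVdd = 4.0 * p_eps[p] * (-12.0*s12 + 6.0*s6) / d;
        terms[4] += V;
      }
      double fac = -dVdd / d;
      f[3*i] += fac*dx; f[3*i+1] += fac*dy; f[3*i+2] += fac*dz;
      f[3*j] -= fac*dx; f[3*j+1] -= fac*dy; f[3*j+2] -= fac*dz;
    }

    // generic 12-6 (class table), shifted at the per-pair cutoff
    for (size_t p = 0; p < nb_lj_i.size(); ++p) {
      int i = nb_lj_i[p], j = nb_lj_j[p];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      mind(dx, dy, dz);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= lj_rc2[p]) continue;
      if (d2 < 1e-12) stop("overlapping beads in nonbonded interaction");
      double s2 = lj_sig2[p] / d2, s6 = s2*s2*s2, s12 = s6*s6;
      terms[5] += lj_eps4[p]*(s12 - s6) - lj_vshift[p];
      double fac = lj_eps4[p]*(12.0*s12 - 6.0*s6) / d2;
      f[3*i] += fac*dx; f[3*i+1] += fac*dy; f[3*i+2] += fac*dz;
      f[3*j] -= fac*dx; f[3*j+1] -= fac*dy; f[3*j+2] -= fac*dz;
    }

    // screened Coulomb, shifted at rc_e
    const double rce2 = rc_e * rc_e;
    const double inv_lam = 1.0 / lambda_D;
    for (size_t p = 0; p < nb_e_i.size(); ++p) {
      int i = nb_e_i[p], j = nb_e_j[p];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      mind(dx, dy, dz);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= rce2) continue;
      double d = std::sqrt(d2);
      if (d < 1e-6) stop("overlapping charged beads");
      double V = e_pref[p] / d * std::exp(-d * inv_lam);
      terms[3] += V - e_vshift[p];
      double fac = V * (1.0/d + inv_lam) / d;
      f[3*i] += fac*dx; f[3*i+1] += fac*dy; f[3*i+2] += fac*dz;
      f[3*j] -= fac*dx; f[3*j+1] -= fac*dy; f[3*j+2] -= fac*dz;
    }

    return terms[0]+terms[1]+terms[2]+terms[3]+terms[4]+terms[5];
  }
};

static FF unpack(List pack, NumericVector coords, double box) {
  FF ff;
  ff.n = coords.size() / 3;
  ff.box = box;
  ff.charge = as<std::vector<double>>(pack["charge"]);
  ff.mass = as<std::vector<double>>(pack["mass"]);
  ff.cls = as<std::vector<int>>(pack["class"]);
  IntegerMatrix B = pack["bonds"];
  for (int b = 0; b < B.nrow(); ++b) { ff.b_i.push_back(B(b,0)); ff.b_j.push_back(B(b,1)); }
  ff.b_k = as<std::vector<double>>(pack["bond_k"]);
  ff.b_d0 = as<std::vector<double>>(pack["bond_d0"]);
  IntegerMatrix A = pack["angles"];
  for (int a = 0; a < A.nrow(); ++a) {
    ff.a_i.push_back(A(a,0)); ff.a_j.push_back(A(a,1)); ff.a_k.push_back(A(a,2));
  }
  ff.a_kt = as<std::vector<double>>(pack["angle_k"]);
  ff.a_t0 = as<std::vector<double>>(pack["angle_t0"]);
  IntegerMatrix D = pack["dihedrals"];
  for (int d = 0; d < D.nrow(); ++d) {
    ff.d_i.push_back(D(d,0)); ff.d_j.push_back(D(d,1));
    ff.d_k.push_back(D(d,2)); ff.d_l.push_back(D(d,3));
    ff.d_n.push_back(D(d,4));
  }
  ff.d_km = as<std::vector<double>>(pack["dihedral_k"]);
  ff.d_del = as<std::vector<double>>(pack["dihedral_delta"]);
  IntegerMatrix P = pack["pairs"];
  for (int p = 0; p < P.nrow(); ++p) {
    ff.p_i.push_back(P(p,0)); ff.p_j.push_back(P(p,1)); ff.p_form.push_back(P(p,2));
  }
  ff.p_eps = as<std::vector<double>>(pack["pair_eps"]);
  ff.p_sig = as<std::vector<double>>(pack["pair_sigma"]);
  NumericMatrix TE = pack["table_eps"], TS = pack["table_sigma"];
  ff.ncls = TE.nrow();
  ff.tab_eps = as<std::vector<double>>(NumericVector(TE));
  ff.tab_sig = as<std::vector<double>>(NumericVector(TS));
  ff.excl_bonded = as<std::vector<double>>(pack["excl_bonded"]);
  ff.excl_pair = as<std::vector<double>>(pack["excl_pair"]);
  ff.eps_d = as<double>(pack["eps_d"]);
  ff.lambda_D = as<double>(pack["lambda_D"]);
  ff.rc_e = as<double>(pack["rc_e"]);
  ff.rc_lj = as<double>(pack["rc_lj"]);
  ff.skin = as<double>(pack["skin"]);
  return ff;
}

// [[Rcpp::export(name = ".cg_energy_forces")]]
List cg_energy_forces(NumericVector coords, List pack, double box) {
  FF ff = unpack(pack, coords, box);
  std::vector<double> x = as<std::vector<double>>(coords);
  std::vector<double> f(x.size());
  double terms[6];
  double E = ff.compute(x, f, terms);
  NumericVector fout = wrap(f);
  fout.attr("dim") = IntegerVector::create(3, ff.n);
  return List::create(
    _["energy"] = E,
    _["terms"] = NumericVector::create(
      _["bond"] = terms[0], _["angle"] = terms[1], _["dihedral"] = terms[2],
      _["electrostatic"] = terms[3], _["pair"] = terms[4],
      _["nonbonded"] = terms[5]),
    _["forces"] = fout);
}

// Steepest descent with backtracking line search.
// [[Rcpp::export(name = ".cg_minimize")]]
List cg_minimize(NumericVector coords, List pack, double box,
                 int max_iter, double ftol, double step0) {
  FF ff = unpack(pack, coords, box);
  std::vector<double> x = as<std::vector<double>>(coords);
  std::vector<double> f(x.size()), xtry(x.size());
  double terms[6];
  double E = ff.compute(x, f, terms);
  if (!std::isfinite(E)) stop("non-finite energy at start of minimisation");
  double step = step0;
  int it = 0;
  for (; it < max_iter; ++it) {
    double fmax = 0;
    for (size_t i = 0; i < f.size(); ++i) fmax = std::max(fmax, std::fabs(f[i]));
    if (fmax < ftol) break;
    for (size_t i = 0; i < x.size(); ++i)
      xtry[i] = x[i] + step * f[i] / fmax;
    std::vector<double> ftry(x.size());
    double Etry = ff.compute(xtry, ftry, terms);
    if (std::isfinite(Etry) && Etry < E) {
      x.swap(xtry); f.swap(ftry); E = Etry;
      step = std::min(step * 1.2, 10 * step0);
    } else {
      step *= 0.5;
      if (step < 1e-10) break;
    }
  }
  NumericVector xout = wrap(x);
  xout.attr("dim") = IntegerVector::create(3, ff.n);
  return List::create(_["coords"] = xout, _["energy"] = E,
                      _["iterations"] = it);
}

// Explicit Marsaglia polar Gaussian on top of mt19937_64: avoids the
// implementation-defined std::normal_distribution and is ~2x faster.
struct Gauss {
  std::mt19937_64& rng;
  double spare = 0; bool has_spare = false;
  explicit Gauss(std::mt19937_64& r) : rng(r) {}
  inline double u01() { return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * u01() - 1.0; v = 2.0 * u01() - 1.0;
      s = u*u + v*v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m; has_spare = true;
    return u * m;
  }
};

// BAOAB Langevin integrator.  dt in ps, friction in 1/ps, T in K.
// [[Rcpp::export(name = ".cg_langevin")]]
List cg_langevin(NumericVector coords, List pack, double box,
                 double dt, double friction, double temperature,
                 int n_steps, int save_every, int seed,
                 Nullable<NumericVector> vel0) {
  FF ff = unpack(pack, coords, box);
  const int n = ff.n;
  const double kB = 0.008314462618;
  std::vector<double> x = as<std::vector<double>>(coords);
  std::vector<double> v(3*n, 0.0), f(3*n);
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1);
  Gauss gauss(rng);
  if (vel0.isNotNull()) {
    v = as<std::vector<double>>(NumericVector(vel0));
  } else if (temperature > 0) {
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kB * temperature / ff.mass[i]);
      for (int k = 0; k < 3; ++k) v[3*i+k] = s * gauss();
    }
  }
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1*c1);
  double terms[6];
  double E = ff.compute(x, f, terms);

  int nframes = n_steps / save_every;
  NumericVector frames((R_xlen_t)nframes * 3 * n);
  NumericVector times(nframes), epot(nframes), ekin(nframes);
  int fr = 0;

  for (int s = 1; s <= n_steps; ++s) {
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] += 0.5 * dt * f[3*i+k] / ff.mass[i];
    // A
    for (size_t i = 0; i < x.size(); ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (friction > 0 && temperature > 0) {
      for (int i = 0; i < n; ++i) {
        double sv = std::sqrt(kB * temperature / ff.mass[i]);
        for (int k = 0; k < 3; ++k)
          v[3*i+k] = c1 * v[3*i+k] + c2 * sv * gauss();
      }
    } else if (friction > 0) {
      for (size_t i = 0; i < v.size(); ++i) v[i] *= c1;
    }
    // A
    for (size_t i = 0; i < x.size(); ++i) x[i] += 0.5 * dt * v[i];
    E = ff.compute(x, f, terms);
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] += 0.5 * dt * f[3*i+k] / ff.mass[i];

    if (!std::isfinite(E))
      stop("simulation blew up at step %d (non-finite energy)", s);
    if (s % save_every == 0 && fr < nframes) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          ke += 0.5 * ff.mass[i] * v[3*i+k] * v[3*i+k];
      for (int i = 0; i < 3*n; ++i) frames[(R_xlen_t)fr*3*n + i] = x[i];
      times[fr] = s * dt; epot[fr] = E; ekin[fr] = ke;
      ++fr;
    }
  }
  NumericVector xout = wrap(x), vout = wrap(v);
  xout.attr("dim") = IntegerVector::create(3, n);
  vout.attr("dim") = IntegerVector::create(3, n);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["coords"] = xout, _["velocities"] = vout,
                      _["n_frames"] = fr);
}
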