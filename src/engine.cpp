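// Metropolis NPT Monte Carlo engine for the coarse-grained bilayer model.
//
// Bead kinds are coded 0 = head, 1 = tail, 2 = solvent.  All energies are in
// epsilon, lengths in sigma_LJ (tail bead), k_B = 1.  Periodic boundaries on
// all three axes, minimum-image convention.  Randomness comes from R's RNG
// so that a single set.seed() call on the R side determines a whole run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct ForceField {
  int bond_style;              // 0 = FENE, 1 = harmonic
  double nu_fene, r0, drm;     // FENE parameters
  double hk, hr0;              // harmonic-bond parameters
  double nu_ba;                // bond-angle strength
  bool has_angles;
  // pair table, flattened 3x3 by kind: [3*a + b]
  double eps[9], sig2[9], rc[9], rc2[9], shift[9];
  int active[9];
  double maxcut;               // largest active cutoff distance
};

inline int pidx(int a, int b) { return 3 * a + b; }

ForceField parse_ff(const List& ffr) {
  ForceField ff;
  ff.bond_style = as<int>(ffr["bond_style"]);
  ff.nu_fene = as<double>(ffr["nu_fene"]);
  ff.r0 = as<double>(ffr["r0"]);
  ff.drm = as<double>(ffr["dr_m"]);
  ff.hk = as<double>(ffr["harmonic_k"]);
  ff.hr0 = as<double>(ffr["harmonic_r0"]);
  ff.nu_ba = as<double>(ffr["nu_ba"]);
  ff.has_angles = ff.nu_ba != 0.0;
  NumericMatrix eps = ffr["epsilon"], sig = ffr["sigma"], rcm = ffr["rc_mult"];
  IntegerMatrix act = ffr["active"];
  ff.maxcut = 0.0;
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      int t = pidx(a, b);
      ff.active[t] = act(a, b);
      ff.eps[t] = eps(a, b);
      double s = sig(a, b);
      ff.sig2[t] = s * s;
      double rcut = rcm(a, b) * s;
      ff.rc[t] = rcut;
      ff.rc2[t] = rcut * rcut;
      // shifted potential: subtract V_LJ(r_c); (sigma/r_c)^6 = rc_mult^-6
      double u6 = std::pow(rcm(a, b), -6.0);
      ff.shift[t] = eps(a, b) * (u6 * u6 - 2.0 * u6);
      if (ff.active[t] && rcut > ff.maxcut) ff.maxcut = rcut;
    }
  }
  return ff;
}

struct System {
  int N;
  std::vector<double> px, py, pz;
  std::vector<int> kind;
  double L[3];
  ForceField ff;

  std::vector<int> bi, bj;                 // bonds
  std::vector<int> ai, aj, ak;             // angle triples
  std::vector<std::vector<int> > bonds_of; // bead -> bond indices
  std::vector<std::vector<int> > angles_of;
  std::vector<std::vector<int> > excl;     // bead -> directly bonded partners

  bool has_well;
  double wk, wc[3];

  // cell list
  bool use_cells;
  int nc[3];
  std::vector<std::vector<int> > cells;
  std::vector<int> cell_of;

  double mi(double d, int ax) const {
    return d - L[ax] * std::nearbyint(d / L[ax]);
  }

  double dist2(double x1, double y1, double z1, int j) const {
    double dx = mi(x1 - px[j], 0), dy = mi(y1 - py[j], 1), dz = mi(z1 - pz[j], 2);
    return dx * dx + dy * dy + dz * dz;
  }

  void wrap(double& x, double& y, double& z) const {
    x -= L[0] * std::floor(x / L[0]);
    y -= L[1] * std::floor(y / L[1]);
    z -= L[2] * std::floor(z / L[2]);
  }

  int cell_index(double x, double y, double z) const {
    int cx = (int)std::floor(x / L[0] * nc[0]); if (cx >= nc[0]) cx = nc[0] - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(y / L[1] * nc[1]); if (cy >= nc[1]) cy = nc[1] - 1; if (cy < 0) cy = 0;
    int cz = (int)std::floor(z / L[2] * nc[2]); if (cz >= nc[2]) cz = nc[2] - 1; if (cz < 0) cz = 0;
    return (cx * nc[1] + cy) * nc[2] + cz;
  }

  void build_cells() {
    use_cells = false;
    if (ff.maxcut <= 0.0) return;
    for (int a = 0; a < 3; ++a) {
      nc[a] = (int)std::floor(L[a] / ff.maxcut);
      if (nc[a] < 3) return;  // brute-force fallback for small boxes
    }
    use_cells = true;
    cells.assign((size_t)nc[0] * nc[1] * nc[2], std::vector<int>());
    cell_of.assign(N, -1);
    for (int i = 0; i < N; ++i) {
      int c = cell_index(px[i], py[i], pz[i]);
      cells[c].push_back(i);
      cell_of[i] = c;
    }
  }

  void cell_move(int i, double x, double y, double z) {
    if (!use_cells) return;
    int c = cell_index(x, y, z);
    if (c == cell_of[i]) return;
    std::vector<int>& old = cells[cell_of[i]];
    old.erase(std::find(old.begin(), old.end(), i));
    cells[c].push_back(i);
    cell_of[i] = c;
  }

  bool excluded(int i, int j) const {
    const std::vector<int>& e = excl[i];
    return std::find(e.begin(), e.end(), j) != e.end();
  }

  double pair_pot(double r2, int t) const {
    if (!ff.active[t] || r2 >= ff.rc2[t]) return 0.0;
    double s2r = ff.sig2[t] / r2;
    double x6 = s2r * s2r * s2r;
    return ff.eps[t] * (x6 * x6 - 2.0 * x6) - ff.shift[t];
  }

  // soft-core energy of bead i as if located at (x,y,z)
  double local_pair_energy(int i, double x, double y, double z) const {
    double e = 0.0;
    int ki = kind[i];
    if (!use_cells) {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        int t = pidx(ki, kind[j]);
        if (!ff.active[t]) continue;
        double r2 = dist2(x, y, z, j);
        if (r2 < ff.rc2[t] && !excluded(i, j)) e += pair_pot(r2, t);
      }
      return e;
    }
    int cx = (int)std::floor(x / L[0] * nc[0]); if (cx >= nc[0]) cx = nc[0] - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(y / L[1] * nc[1]); if (cy >= nc[1]) cy = nc[1] - 1; if (cy < 0) cy = 0;
    int cz = (int)std::floor(z / L[2] * nc[2]); if (cz >= nc[2]) cz = nc[2] - 1; if (cz < 0) cz = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int ux = (cx + dx + nc[0]) % nc[0];
          int uy = (cy + dy + nc[1]) % nc[1];
          int uz = (cz + dz + nc[2]) % nc[2];
          const std::vector<int>& cell = cells[(ux * nc[1] + uy) * nc[2] + uz];
          for (size_t m = 0; m < cell.size(); ++m) {
            int j = cell[m];
            if (j == i) continue;
            int t = pidx(ki, kind[j]);
            if (!ff.active[t]) continue;
            double r2 = dist2(x, y, z, j);
            if (r2 < ff.rc2[t] && !excluded(i, j)) e += pair_pot(r2, t);
          }
        }
    return e;
  }

  double total_pair_energy() const {
    double e = 0.0;
    if (!use_cells) {
      for (int i = 0; i < N; ++i) {
        int ki = kind[i];
        for (int j = i + 1; j < N; ++j) {
          int t = pidx(ki, kind[j]);
          if (!ff.active[t]) continue;
          double r2 = dist2(px[i], py[i], pz[i], j);
          if (r2 < ff.rc2[t] && !excluded(i, j)) e += pair_pot(r2, t);
        }
      }
      return e;
    }
    for (int i = 0; i < N; ++i) {
      double x = px[i], y = py[i], z = pz[i];
      int ki = kind[i];
      int c = cell_of[i];
      int cz0 = c % nc[2], cy0 = (c / nc[2]) % nc[1], cx0 = c / (nc[1] * nc[2]);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int ux = (cx0 + dx + nc[0]) % nc[0];
            int uy = (cy0 + dy + nc[1]) % nc[1];
            int uz = (cz0 + dz + nc[2]) % nc[2];
            const std::vector<int>& cell = cells[(ux * nc[1] + uy) * nc[2] + uz];
            for (size_t m = 0; m < cell.size(); ++m) {
              int j = cell[m];
              if (j <= i) continue;
              int t = pidx(ki, kind[j]);
              if (!ff.active[t]) continue;
              double r2 = dist2(x, y, z, j);
              if (r2 < ff.rc2[t] && !excluded(i, j)) e += pair_pot(r2, t);
            }
          }
    }
    return e;
  }

  double bond_pot(double r, bool& bad) const {
    if (ff.bond_style == 1) {
      double d = r - ff.hr0;
      return 0.5 * ff.hk * d * d;
    }
    double u = (r - ff.r0) / ff.drm;
    if (u * u >= 1.0) { bad = true; return R_PosInf; }
    return -0.5 * ff.nu_fene * ff.drm * ff.drm * std::log(1.0 - u * u);
  }

  double bond_len(int b, int moved = -1, double x = 0, double y = 0, double z = 0) const {
    int i = bi[b], j = bj[b];
    double xi = (i == moved) ? x : px[i], yi = (i == moved) ? y : py[i], zi = (i == moved) ? z : pz[i];
    double xj = (j == moved) ? x : px[j], yj = (j == moved) ? y : py[j], zj = (j == moved) ? z : pz[j];
    double dx = mi(xi - xj, 0), dy = mi(yi - yj, 1), dz = mi(zi - zj, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  // angle energy for triple index a, with optional substituted position for one bead
  double angle_pot(int a, int moved = -1, double x = 0, double y = 0, double z = 0) const {
    int i = ai[a], j = aj[a], k = ak[a];
    double xi = (i == moved) ? x : px[i], yi = (i == moved) ? y : py[i], zi = (i == moved) ? z : pz[i];
    double xj = (j == moved) ? x : px[j], yj = (j == moved) ? y : py[j], zj = (j == moved) ? z : pz[j];
    double xk = (k == moved) ? x : px[k], yk = (k == moved) ? y : py[k], zk = (k == moved) ? z : pz[k];
    double ux = mi(xj - xi, 0), uy = mi(yj - yi, 1), uz = mi(zj - zi, 2);
    double vx = mi(xk - xj, 0), vy = mi(yk - yj, 1), vz = mi(zk - zj, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    return ff.nu_ba * (1.0 - c);  // theta = 0 for a straight chain
  }

  double well_pot(double x, double y, double z) const {
    if (!has_well) return 0.0;
    double dx = mi(x - wc[0], 0), dy = mi(y - wc[1], 1), dz = mi(z - wc[2], 2);
    return 0.5 * wk * (dx * dx + dy * dy + dz * dz);
  }

  double total_bond_energy(bool& bad, int& bad_bond) const {
    double e = 0.0;
    for (size_t b = 0; b < bi.size(); ++b) {
      bool viol = false;
      e += bond_pot(bond_len((int)b), viol);
      if (viol) { bad = true; bad_bond = (int)b; return e; }
    }
    return e;
  }

  double total_angle_energy() const {
    double e = 0.0;
    if (!ff.has_angles) return 0.0;
    for (size_t a = 0; a < ai.size(); ++a) e += angle_pot((int)a);
    return e;
  }

  double total_well_energy() const {
    if (!has_well) return 0.0;
    double e = 0.0;
    for (int i = 0; i < N; ++i) e += well_pot(px[i], py[i], pz[i]);
    return e;
  }

  double total_energy(bool& bad, int& bad_bond) {
    double e = total_bond_energy(bad, bad_bond);
    if (bad) return e;
    e += total_angle_energy();
    e += total_pair_energy();
    e += total_well_energy();
    return e;
  }

  // energy change of moving bead i to (x,y,z); +Inf and bad=true on a FENE
  // domain violation at the trial position
  double displace_delta(int i, double x, double y, double z, bool& bad) {
    double e_old = local_pair_energy(i, px[i], py[i], pz[i]);
    double e_new = local_pair_energy(i, x, y, z);
    const std::vector<int>& bl = bonds_of[i];
    for (size_t m = 0; m < bl.size(); ++m) {
      bool v = false;
      e_old += bond_pot(bond_len(bl[m]), v);
      double en = bond_pot(bond_len(bl[m], i, x, y, z), v);
      if (v) { bad = true; return R_PosInf; }
      e_new += en;
    }
    if (ff.has_angles) {
      const std::vector<int>& al = angles_of[i];
      for (size_t m = 0; m < al.size(); ++m) {
        e_old += angle_pot(al[m]);
        e_new += angle_pot(al[m], i, x, y, z);
      }
    }
    if (has_well) {
      e_old += well_pot(px[i], py[i], pz[i]);
      e_new += well_pot(x, y, z);
    }
    return e_new - e_old;
  }
};

System make_system(NumericMatrix pos, IntegerVector kind, NumericVector box,
                   IntegerMatrix bonds, IntegerMatrix angles,
                   const List& ffr, SEXP wellr) {
  System s;
  s.N = pos.nrow();
  s.px.resize(s.N); s.py.resize(s.N); s.pz.resize(s.N);
  s.kind.resize(s.N);
  for (int a = 0; a < 3; ++a) s.L[a] = box[a];
  for (int i = 0; i < s.N; ++i) {
    s.px[i] = pos(i, 0); s.py[i] = pos(i, 1); s.pz[i] = pos(i, 2);
    s.wrap(s.px[i], s.py[i], s.pz[i]);
    s.kind[i] = kind[i];
  }
  s.ff = parse_ff(ffr);
  bool excl_bonded = true;
  if (ffr.containsElementNamed("exclude_bonded"))
    excl_bonded = as<bool>(ffr["exclude_bonded"]);
  int B = bonds.nrow();
  s.bi.resize(B); s.bj.resize(B);
  s.bonds_of.assign(s.N, std::vector<int>());
  s.excl.assign(s.N, std::vector<int>());
  for (int b = 0; b < B; ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    s.bi[b] = i; s.bj[b] = j;
    s.bonds_of[i].push_back(b);
    s.bonds_of[j].push_back(b);
    if (excl_bonded) {
      s.excl[i].push_back(j);
      s.excl[j].push_back(i);
    }
  }
  int A = angles.nrow();
  s.ai.resize(A); s.aj.resize(A); s.ak.resize(A);
  s.angles_of.assign(s.N, std::vector<int>());
  for (int a = 0; a < A; ++a) {
    s.ai[a] = angles(a, 0) - 1; s.aj[a] = angles(a, 1) - 1; s.ak[a] = angles(a, 2) - 1;
    s.angles_of[s.ai[a]].push_back(a);
    s.angles_of[s.aj[a]].push_back(a);
    s.angles_of[s.ak[a]].push_back(a);
  }
  s.has_well = false;
  if (wellr != R_NilValue) {
    List w(wellr);
    s.has_well = true;
    s.wk = as<double>(w["k"]);
    NumericVector c = w["center"];
    s.wc[0] = c[0]; s.wc[1] = c[1]; s.wc[2] = c[2];
  }
  s.build_cells();
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix pos, IntegerVector kind, NumericVector box,
                      IntegerMatrix bonds, IntegerMatrix angles, List ffr,
                      SEXP wellr) {
  System s = make_system(pos, kind, box, bonds, angles, ffr, wellr);
  bool bad = false; int bad_bond = -1;
  double eb = s.total_bond_energy(bad, bad_bond);
  if (bad)
    stop("FENE bond %d (beads %d-%d) outside admissible extension range",
         bad_bond + 1, s.bi[bad_bond] + 1, s.bj[bad_bond] + 1);
  double ea = s.total_angle_energy();
  double ep = s.total_pair_energy();
  double ew = s.total_well_energy();
  return List::create(_["total"] = eb + ea + ep + ew, _["bond"] = eb,
                      _["angle"] = ea, _["pair"] = ep, _["well"] = ew);
}

// [[Rcpp::export]]
double cpp_displace_delta(NumericMatrix pos, IntegerVector kind, NumericVector box,
                          IntegerMatrix bonds, IntegerMatrix angles, List ffr,
                          SEXP wellr, int bead, NumericVector newpos) {
  System s = make_system(pos, kind, box, bonds, angles, ffr, wellr);
  double x = newpos[0], y = newpos[1], z = newpos[2];
  s.wrap(x, y, z);
  bool bad = false;
  double d = s.displace_delta(bead - 1, x, y, z, bad);
  if (bad)
    stop("proposed displacement of bead %d breaks a FENE bond", bead);
  return d;
}

// [[Rcpp::export]]
double cpp_min_pair_ratio(NumericMatrix pos, IntegerVector kind, NumericVector box,
                          IntegerMatrix bonds, List ffr) {
  // minimum over active, non-bonded pairs of r / sigma_pair
  IntegerMatrix angles(0, 3);
  System s = make_system(pos, kind, box, bonds, angles, ffr, R_NilValue);
  double best = R_PosInf;
  for (int i = 0; i < s.N; ++i) {
    for (int j = i + 1; j < s.N; ++j) {
      int t = pidx(s.kind[i], s.kind[j]);
      if (!s.ff.active[t] || s.excluded(i, j)) continue;
      double r2 = s.dist2(s.px[i], s.py[i], s.pz[i], j);
      double ratio = std::sqrt(r2 / s.ff.sig2[t]);
      if (ratio < best) best = ratio;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, IntegerVector kind, NumericVector box,
                IntegerMatrix bonds, IntegerMatrix angles, List ffr, SEXP wellr,
                double T, double P, int sweeps, double dmax0, double boxmax,
                LogicalVector fixed_axes, LogicalVector move_axes,
                int sample_every, bool adapt, double target_acc) {
  System s = make_system(pos, kind, box, bonds, angles, ffr, wellr);
  RNGScope rng;
  bool bad = false; int bad_bond = -1;
  double E = s.total_energy(bad, bad_bond);
  if (bad)
    stop("initial configuration has FENE bond %d outside its admissible range",
         bad_bond + 1);

  double dmax = dmax0;
  std::vector<int> free_axes;
  for (int a = 0; a < 3; ++a) if (!fixed_axes[a]) free_axes.push_back(a);

  long disp_att = 0, disp_acc = 0, box_att = 0, box_acc = 0;
  long win_att = 0, win_acc = 0;

  int nrec = (sample_every > 0 && sweeps > 0) ? (sweeps / sample_every) : 0;
  NumericMatrix series(nrec, 6);
  int rec = 0;

  std::vector<double> save_col;

  for (int sweep = 1; sweep <= sweeps; ++sweep) {
    // one attempted displacement per bead
    for (int i = 0; i < s.N; ++i) {
      double x = s.px[i], y = s.py[i], z = s.pz[i];
      if (move_axes[0]) x += dmax * (2.0 * unif_rand() - 1.0);
      if (move_axes[1]) y += dmax * (2.0 * unif_rand() - 1.0);
      if (move_axes[2]) z += dmax * (2.0 * unif_rand() - 1.0);
      s.wrap(x, y, z);
      ++disp_att; ++win_att;
      bool viol = false;
      double dU = s.displace_delta(i, x, y, z, viol);
      if (viol) continue;  // broken bond: reject
      if (dU <= 0.0 || unif_rand() < std::exp(-dU / T)) {
        s.px[i] = x; s.py[i] = y; s.pz[i] = z;
        s.cell_move(i, x, y, z);
        E += dU;
        ++disp_acc; ++win_acc;
      }
    }

    // one box move per non-fixed axis, ln-L proposal:
    // accept with min(1, exp(-[dU + P dV - N T ln(V'/V)]/T))
    for (size_t m = 0; m < free_axes.size(); ++m) {
      int ax = free_axes[m];
      double delta = boxmax * (2.0 * unif_rand() - 1.0);
      double fac = std::exp(delta);
      double Lold = s.L[ax];
      double Vold = s.L[0] * s.L[1] * s.L[2];
      ++box_att;
      // scale coordinates affinely along the axis
      std::vector<double>& col = (ax == 0) ? s.px : ((ax == 1) ? s.py : s.pz);
      save_col = col;
      for (int i = 0; i < s.N; ++i) col[i] *= fac;
      s.L[ax] = Lold * fac;
      s.build_cells();
      bool viol = false; int vb = -1;
      double Enew = s.total_energy(viol, vb);
      double Vnew = s.L[0] * s.L[1] * s.L[2];
      bool accept = false;
      if (!viol) {
        double arg = (Enew - E) + P * (Vnew - Vold) - s.N * T * delta;
        accept = (arg <= 0.0) || (unif_rand() < std::exp(-arg / T));
      }
      if (accept) {
        E = Enew;
        ++box_acc;
      } else {
        col = save_col;
        s.L[ax] = Lold;
        s.build_cells();
      }
    }

    if (adapt && sweep % 50 == 0 && win_att > 0) {
      double acc = (double)win_acc / (double)win_att;
      if (acc > target_acc) dmax *= 1.1; else dmax *= 0.9;
      double lim = 0.25 * std::min(s.L[0], std::min(s.L[1], s.L[2]));
      if (dmax > lim) dmax = lim;
      if (dmax < 1e-6) dmax = 1e-6;
      win_att = 0; win_acc = 0;
    }

    if (sample_every > 0 && sweep % sample_every == 0 && rec < nrec) {
      series(rec, 0) = sweep;
      series(rec, 1) = s.L[0];
      series(rec, 2) = s.L[1];
      series(rec, 3) = s.L[2];
      series(rec, 4) = E;
      series(rec, 5) = s.L[0] * s.L[1] * s.L[2];
      ++rec;
    }
  }

  NumericMatrix out_pos(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out_pos(i, 0) = s.px[i]; out_pos(i, 1) = s.py[i]; out_pos(i, 2) = s.pz[i];
  }
  return List::create(
    _["positions"] = out_pos,
    _["box"] = NumericVector::create(s.L[0], s.L[1], s.L[2]),
    _["series"] = series,
    _["energy"] = E,
    _["acc_displacement"] = disp_att > 0 ? (double)disp_acc / disp_att : NA_REAL,
    _["acc_box"] = box_att > 0 ? (double)box_acc / box_att : NA_REAL,
    _["n_box_moves"] = (double)box_att,
    _["dmax_final"] = dmax);
}
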