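// Intramolecular MM engine: AMBER-style functional form over precompiled
// term lists. Energies in kcal/mol, lengths in Angstrom, angles in radians.
// Parameter vectors ("theta") pack the bonded parameters in the order
// [bond_k, bond_r0, angle_k, angle_theta0, torsion_V, torsion_gamma];
// periodicities, vdW, charges and 1-4 scalings are frozen at compile time.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

inline Vec3 vat(const double* x, int i) {
  return Vec3(x[3 * i], x[3 * i + 1], x[3 * i + 2]);
}
inline void add_to(double* F, int i, const Vec3& v) {
  F[3 * i] += v.x; F[3 * i + 1] += v.y; F[3 * i + 2] += v.z;
}

class Engine {
public:
  int n;  // atoms
  std::vector<int> bi, bj, bt;              // bonds: atoms + type index
  std::vector<int> ai, aj, ak, at;          // angles
  std::vector<int> ti, tj, tk, tl, tc;      // torsion component instances
  std::vector<int> comp_n;                  // periodicity per component type
  std::vector<int> nbi, nbj;                // nonbonded pair list
  std::vector<double> qq, eps, rmin;        // pair coefficients (scaling folded in)
  int nbt, nat, ntc;                        // type counts
  // current bonded parameters
  std::vector<double> bk, br0, angk, angt0, V, gam;

  Engine(const List& sys) {
    n = as<int>(sys["natoms"]);
    bi = as<std::vector<int> >(sys["bond_i"]);
    bj = as<std::vector<int> >(sys["bond_j"]);
    bt = as<std::vector<int> >(sys["bond_t"]);
    ai = as<std::vector<int> >(sys["angle_i"]);
    aj = as<std::vector<int> >(sys["angle_j"]);
    ak = as<std::vector<int> >(sys["angle_k"]);
    at = as<std::vector<int> >(sys["angle_t"]);
    ti = as<std::vector<int> >(sys["tor_i"]);
    tj = as<std::vector<int> >(sys["tor_j"]);
    tk = as<std::vector<int> >(sys["tor_k"]);
    tl = as<std::vector<int> >(sys["tor_l"]);
    tc = as<std::vector<int> >(sys["tor_c"]);
    comp_n = as<std::vector<int> >(sys["comp_n"]);
    nbi = as<std::vector<int> >(sys["nb_i"]);
    nbj = as<std::vector<int> >(sys["nb_j"]);
    qq = as<std::vector<double> >(sys["nb_qq"]);
    eps = as<std::vector<double> >(sys["nb_eps"]);
    rmin = as<std::vector<double> >(sys["nb_rmin"]);
    nbt = as<int>(sys["n_bond_types"]);
    nat = as<int>(sys["n_angle_types"]);
    ntc = as<int>(sys["n_tor_comps"]);
  }

  int ntheta() const { return 2 * nbt + 2 * nat + 2 * ntc; }

  void set_theta(const NumericVector& th) {
    if ((int)th.size() != ntheta())
      stop("theta length %d does not match packing map (expected %d)",
           (int)th.size(), ntheta());
    const double* p = th.begin();
    bk.assign(p, p + nbt); p += nbt;
    br0.assign(p, p + nbt); p += nbt;
    angk.assign(p, p + nat); p += nat;
    angt0.assign(p, p + nat); p += nat;
    V.assign(p, p + ntc); p += ntc;
    gam.assign(p, p + ntc);
  }

  // Energy with optional per-class components and forces (F = -grad E).
  // comps: bond, angle, torsion, lj, coulomb.
  double energy(const double* x, double* F, double* comps) const {
    double Eb = 0, Ea = 0, Et = 0, Elj = 0, Ec = 0;
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      Vec3 d = vat(x, bi[b]) - vat(x, bj[b]);
      double r = d.norm();
      double dr = r - br0[bt[b]];
      double k = bk[bt[b]];
      Eb += k * dr * dr;
      if (F) {
        double fs = -2.0 * k * dr / r;
        add_to(F, bi[b], d * fs);
        add_to(F, bj[b], d * (-fs));
      }
    }
    // angles
    for (size_t a = 0; a < ai.size(); ++a) {
      Vec3 u = vat(x, ai[a]) - vat(x, aj[a]);
      Vec3 v = vat(x, ak[a]) - vat(x, aj[a]);
      double nu = u.norm(), nv = v.norm();
      double ct = u.dot(v) / (nu * nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double k = angk[at[a]];
      double dth = th - angt0[at[a]];
      Ea += k * dth * dth;
      if (F) {
        double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
        Vec3 di = (u * (ct / (nu * nu)) - v * (1.0 / (nu * nv))) * (1.0 / st);
        Vec3 dk = (v * (ct / (nv * nv)) - u * (1.0 / (nu * nv))) * (1.0 / st);
        double dEdth = 2.0 * k * dth;
        add_to(F, ai[a], di * (-dEdth));
        add_to(F, ak[a], dk * (-dEdth));
        add_to(F, aj[a], (di + dk) * dEdth);
      }
    }
    // torsions (one entry per Fourier component instance)
    for (size_t t = 0; t < ti.size(); ++t) {
      Vec3 b1 = vat(x, tj[t]) - vat(x, ti[t]);
      Vec3 b2 = vat(x, tk[t]) - vat(x, tj[t]);
      Vec3 b3 = vat(x, tl[t]) - vat(x, tk[t]);
      Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
      double nb2 = b2.norm();
      double phi = std::atan2(n1.cross(n2).dot(b2) / nb2, n1.dot(n2));
      int c = tc[t];
      int per = comp_n[c];
      double arg = per * phi - gam[c];
      Et += 0.5 * V[c] * (1.0 + std::cos(arg));
      if (F) {
        double dEdphi = -0.5 * V[c] * per * std::sin(arg);
        double in1 = 1.0 / std::max(n1.norm2(), 1e-12);
        double in2 = 1.0 / std::max(n2.norm2(), 1e-12);
        Vec3 dpi = n1 * (-nb2 * in1);
        Vec3 dpl = n2 * (nb2 * in2);
        double p12 = b1.dot(b2) / (nb2 * nb2);
        double p32 = b3.dot(b2) / (nb2 * nb2);
        Vec3 dpj = dpi * (-1.0 - p12) + dpl * p32;
        Vec3 dpk = dpi * p12 - dpl * (1.0 + p32);
        add_to(F, ti[t], dpi * (-dEdphi));
        add_to(F, tj[t], dpj * (-dEdphi));
        add_to(F, tk[t], dpk * (-dEdphi));
        add_to(F, tl[t], dpl * (-dEdphi));
      }
    }
    // nonbonded
    for (size_t p = 0; p < nbi.size(); ++p) {
      Vec3 d = vat(x, nbi[p]) - vat(x, nbj[p]);
      double r2 = d.norm2();
      if (r2 < 1e-12) return R_PosInf;
      double r = std::sqrt(r2);
      double ec = qq[p] / r;
      double s2 = (rmin[p] * rmin[p]) / r2;
      double s6 = s2 * s2 * s2;
      double elj = eps[p] * (s6 * s6 - 2.0 * s6);
      Ec += ec;
      Elj += elj;
      if (F) {
        // dE/dr: coulomb -qq/r^2 ; LJ -12 eps (s12 - s6)/r
        double dEdr = -ec / r - 12.0 * eps[p] * (s6 * s6 - s6) / r;
        Vec3 f = d * (-dEdr / r);
        add_to(F, nbi[p], f);
        add_to(F, nbj[p], f * (-1.0));
      }
    }
    if (comps) {
      comps[0] = Eb; comps[1] = Ea; comps[2] = Et; comps[3] = Elj; comps[4] = Ec;
    }
    return Eb + Ea + Et + Elj + Ec;
  }

  // dE/dtheta for one configuration (length ntheta), plus, when Fref is
  // given, accumulation of d(sum |F - Fref|^2)/dtheta into gF and the force
  // residual sum of squares into floss. F must hold the forces of this
  // configuration (computed beforehand).
  void param_grad(const double* x, double* dE,
                  const double* F, const double* Fref,
                  double* gF, double* floss) const {
    std::vector<double> dF;  // residual 2*(F - Fref)
    if (Fref) {
      dF.resize(3 * n);
      double ss = 0;
      for (int i = 0; i < 3 * n; ++i) {
        double r = F[i] - Fref[i];
        ss += r * r;
        dF[i] = 2.0 * r;
      }
      *floss += ss;
    }
    const double* rf = Fref ? dF.data() : (const double*)0;
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      int t = bt[b];
      Vec3 d = vat(x, bi[b]) - vat(x, bj[b]);
      double r = d.norm();
      double dr = r - br0[t];
      dE[t] += dr * dr;
      dE[nbt + t] += -2.0 * bk[t] * dr;
      if (rf) {
        Vec3 g = d * (1.0 / r);
        Vec3 rdiff(rf[3 * bi[b]] - rf[3 * bj[b]],
                   rf[3 * bi[b] + 1] - rf[3 * bj[b] + 1],
                   rf[3 * bi[b] + 2] - rf[3 * bj[b] + 2]);
        double proj = rdiff.dot(g);
        gF[t] += -2.0 * dr * proj;          // dF/dk
        gF[nbt + t] += 2.0 * bk[t] * proj;  // dF/dr0
      }
    }
    int off = 2 * nbt;
    // angles
    for (size_t a = 0; a < ai.size(); ++a) {
      int t = at[a];
      Vec3 u = vat(x, ai[a]) - vat(x, aj[a]);
      Vec3 v = vat(x, ak[a]) - vat(x, aj[a]);
      double nu = u.norm(), nv = v.norm();
      double ct = u.dot(v) / (nu * nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double dth = th - angt0[t];
      dE[off + t] += dth * dth;
      dE[off + nat + t] += -2.0 * angk[t] * dth;
      if (rf) {
        double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
        Vec3 di = (u * (ct / (nu * nu)) - v * (1.0 / (nu * nv))) * (1.0 / st);
        Vec3 dk = (v * (ct / (nv * nv)) - u * (1.0 / (nu * nv))) * (1.0 / st);
        // sum_a rf_a . D_a with D_j = -(D_i + D_k)
        Vec3 ri = vat(rf, ai[a]), rj = vat(rf, aj[a]), rk2 = vat(rf, ak[a]);
        double proj = (ri - rj).dot(di) + (rk2 - rj).dot(dk);
        gF[off + t] += -2.0 * dth * proj;
        gF[off + nat + t] += 2.0 * angk[t] * proj;
      }
    }
    off = 2 * nbt + 2 * nat;
    // torsions
    for (size_t t = 0; t < ti.size(); ++t) {
      int c = tc[t];
      Vec3 b1 = vat(x, tj[t]) - vat(x, ti[t]);
      Vec3 b2 = vat(x, tk[t]) - vat(x, tj[t]);
      Vec3 b3 = vat(x, tl[t]) - vat(x, tk[t]);
      Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
      double nb2 = b2.norm();
      double phi = std::atan2(n1.cross(n2).dot(b2) / nb2, n1.dot(n2));
      int per = comp_n[c];
      double arg = per * phi - gam[c];
      dE[off + c] += 0.5 * (1.0 + std::cos(arg));
      dE[off + ntc + c] += 0.5 * V[c] * std::sin(arg);
      if (rf) {
        double in1 = 1.0 / std::max(n1.norm2(), 1e-12);
        double in2 = 1.0 / std::max(n2.norm2(), 1e-12);
        Vec3 dpi = n1 * (-nb2 * in1);
        Vec3 dpl = n2 * (nb2 * in2);
        double p12 = b1.dot(b2) / (nb2 * nb2);
        double p32 = b3.dot(b2) / (nb2 * nb2);
        Vec3 dpj = dpi * (-1.0 - p12) + dpl * p32;
        Vec3 dpk = dpi * p12 - dpl * (1.0 + p32);
        double proj = vat(rf, ti[t]).dot(dpi) + vat(rf, tj[t]).dot(dpj) +
                      vat(rf, tk[t]).dot(dpk) + vat(rf, tl[t]).dot(dpl);
        // F_a = (V*per/2) sin(arg) D_a
        gF[off + c] += 0.5 * per * std::sin(arg) * proj;
        gF[off + ntc + c] += -0.5 * V[c] * per * std::cos(arg) * proj;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".hf_energy_forces")]]
List hf_energy_forces(List sys, NumericVector theta, NumericVector pos,
                      bool want_forces) {
  Engine e(sys);
  e.set_theta(theta);
  NumericVector comps(5);
  NumericVector F;
  double E;
  if (want_forces) {
    F = NumericVector(3 * e.n);
    E = e.energy(pos.begin(), F.begin(), comps.begin());
  } else {
    E = e.energy(pos.begin(), (double*)0, comps.begin());
  }
  comps.names() = CharacterVector::create("bond", "angle", "torsion", "lj", "coulomb");
  return List::create(_["energy"] = E, _["components"] = comps, _["forces"] = F);
}

// Energies (and optionally forces) for a batch of configurations.
// confs: 3*natoms x nconf matrix, column-major per configuration.
// [[Rcpp::export(name = ".hf_batch_eval")]]
List hf_batch_eval(List sys, NumericVector theta, NumericMatrix confs,
                   bool want_forces) {
  Engine e(sys);
  e.set_theta(theta);
  int N = confs.ncol();
  NumericVector E(N);
  NumericMatrix F;
  if (want_forces) F = NumericMatrix(3 * e.n, N);
  for (int c = 0; c < N; ++c) {
    E[c] = e.energy(&confs(0, c), want_forces ? &F(0, c) : (double*)0, (double*)0);
  }
  return List::create(_["energies"] = E, _["forces"] = F);
}

// Force-matching loss ingredients over a dataset: model energies, the
// per-configuration energy-derivative matrix dE (ntheta x N), the summed
// force residual square floss = sum_c |F_c - Fref_c|_F^2 and its gradient
// gF (ntheta). The energy-offset profiling and weighting are assembled in R.
// [[Rcpp::export(name = ".hf_fm_parts")]]
List hf_fm_parts(List sys, NumericVector theta, NumericMatrix confs,
                 Rcpp::Nullable<Rcpp::NumericMatrix> Fref_) {
  Engine e(sys);
  e.set_theta(theta);
  int N = confs.ncol();
  int p = e.ntheta();
  bool wantF = Fref_.isNotNull();
  NumericMatrix Fref;
  if (wantF) Fref = NumericMatrix(Fref_);
  NumericVector E(N);
  NumericMatrix dE(p, N);
  NumericVector gF(p);
  double floss = 0;
  std::vector<double> F(3 * e.n);
  for (int c = 0; c < N; ++c) {
    if (wantF) {
      std::fill(F.begin(), F.end(), 0.0);
      E[c] = e.energy(&confs(0, c), F.data(), (double*)0);
      e.param_grad(&confs(0, c), &dE(0, c), F.data(), &Fref(0, c),
                   gF.begin(), &floss);
    } else {
      E[c] = e.energy(&confs(0, c), (double*)0, (double*)0);
      e.param_grad(&confs(0, c), &dE(0, c), (double*)0, (double*)0,
                   (double*)0, (double*)0);
    }
  }
  return List::create(_["energies"] = E, _["dE"] = dE,
                      _["floss"] = floss, _["gF"] = gF);
}

// Metropolis single-atom-displacement sampler. Uses R's RNG so set.seed()
// in the caller makes runs reproducible. Returns the retained frames as a
// 3*natoms x n_samples matrix plus the production acceptance ratio.
// [[Rcpp::export(name = ".hf_mc_sample")]]
List hf_mc_sample(List sys, NumericVector theta, NumericVector start,
                  int n_samples, int stride, double kT,
                  int burnin_sweeps, double max_step, bool tune) {
  Engine e(sys);
  e.set_theta(theta);
  RNGScope scope;
  int n = e.n;
  std::vector<double> x(start.begin(), start.end());
  double Ecur = e.energy(x.data(), (double*)0, (double*)0);
  if (!R_finite(Ecur)) stop("non-finite energy at the starting configuration");
  long acc = 0, tot = 0;
  long win_acc = 0, win_tot = 0;
  NumericMatrix frames(3 * n, n_samples);
  NumericVector energies(n_samples);
  double accept_target = 0.40;

  auto sweep = [&](bool tuning) {
    for (int t = 0; t < n; ++t) {
      int a = (int)(unif_rand() * n);
      if (a >= n) a = n - 1;
      double old0 = x[3 * a], old1 = x[3 * a + 1], old2 = x[3 * a + 2];
      x[3 * a] += max_step * norm_rand();
      x[3 * a + 1] += max_step * norm_rand();
      x[3 * a + 2] += max_step * norm_rand();
      double Enew = e.energy(x.data(), (double*)0, (double*)0);
      bool ok = R_finite(Enew) &&
                (Enew <= Ecur || unif_rand() < std::exp(-(Enew - Ecur) / kT));
      if (ok) {
        Ecur = Enew;
        if (!tuning) ++acc;
        ++win_acc;
      } else {
        x[3 * a] = old0; x[3 * a + 1] = old1; x[3 * a + 2] = old2;
      }
      if (!tuning) ++tot;
      ++win_tot;
    }
  };

  for (int s = 0; s < burnin_sweeps; ++s) {
    sweep(true);
    if (tune && win_tot >= 50 * n) {
      double rate = (double)win_acc / win_tot;
      if (rate > accept_target + 0.05) max_step *= 1.2;
      else if (rate < accept_target - 0.05) max_step *= 0.8;
      win_acc = 0; win_tot = 0;
    }
  }
  for (int sN = 0; sN < n_samples; ++sN) {
    for (int s = 0; s < stride; ++s) sweep(false);
    std::copy(x.begin(), x.end(), &frames(0, sN));
    energies[sN] = Ecur;
  }
  double ratio = tot > 0 ? (double)acc / tot : NA_REAL;
  return List::create(_["frames"] = frames, _["acceptance"] = ratio,
                      _["max_step"] = max_step, _["energies"] = energies);
}
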