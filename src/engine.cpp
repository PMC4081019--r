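// Coarse-grained energy/force kernels and Langevin (BAOAB) integrator.
//
// Units: lengths in nm, energies in native-contact units (epsilon), masses in
// model units, kB supplied by the caller.  Periodic minimum-image convention
// is applied to inter-monomer non-bonded pairs only; intra-monomer geometry
// and bonded terms use unwrapped coordinates (molecules are never wrapped).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <sstream>
#include <iomanip>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// xoshiro256** RNG with splitmix64 seeding.  The state is serialisable (four
// 64-bit words as hex strings) so interrupted runs resume bit-identically.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

static CharacterVector rng_state_to_hex(const Xoshiro &rng) {
  CharacterVector out(4);
  for (int i = 0; i < 4; ++i) {
    std::ostringstream ss;
    ss << std::hex << std::setw(16) << std::setfill('0') << rng.s[i];
    out[i] = ss.str();
  }
  return out;
}

static void rng_state_from_hex(Xoshiro &rng, const CharacterVector &st) {
  if (st.size() != 4) stop("rng state must have 4 components");
  for (int i = 0; i < 4; ++i) {
    std::istringstream ss(as<std::string>(st[i]));
    ss >> std::hex >> rng.s[i];
  }
}

// [[Rcpp::export(name = ".rng_init_cpp")]]
CharacterVector rng_init_cpp(double seed) {
  Xoshiro rng;
  rng.seed((uint64_t)seed);
  return rng_state_to_hex(rng);
}

// ---------------------------------------------------------------------------
// Engine specification unpacked from the R-side topology/parameter list.
// ---------------------------------------------------------------------------
struct Engine {
  int n;
  std::vector<int> mono;              // 1 or 2 per bead
  // bonded terms
  std::vector<int> b_i, b_j;          std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;     std::vector<double> a_t0, a_kt;
  std::vector<int> d_i, d_j, d_k, d_l, d_type;
  std::vector<double> d_p0, d_kd;
  std::vector<int> c_i, c_j;          std::vector<double> c_rn, c_eps;
  int link_i = -1, link_j = -1;       double link_r0 = 0.0, link_k = 0.0;
  // non-bonded candidate pairs
  std::vector<int> p_i, p_j;
  std::vector<char> p_inter;
  std::vector<double> p_aq;           // DH prefactor q_i q_j K_coul / eps_r (0 if none)
  std::vector<double> p_heps;         // HP depth lambda * eps_ij (0 if none)
  std::vector<double> p_cut;          // per-pair interaction cutoff
  // parameters
  double box = 0.0;
  double lambdaD = 1.0, elec_cut = 3.0, elec_shift_scale = 0.0,
         elec_dslope = 0.0;
  double hp_r0 = 0.8, hp_C = 10.0, hp_cut = 1.5;
  double rep_sig = 0.4, rep_eps = 1.0, rep_cut = 0.7, rep_shift = 0.0,
         rep_dslope = 0.0;
};

static Engine unpack_engine(const List &spec) {
  Engine e;
  e.n = as<int>(spec["n"]);
  e.mono = as<std::vector<int>>(spec["mono"]);

  IntegerMatrix bi = spec["bonds_idx"];  NumericMatrix bp = spec["bonds_par"];
  for (int r = 0; r < bi.nrow(); ++r) {
    e.b_i.push_back(bi(r, 0)); e.b_j.push_back(bi(r, 1));
    e.b_r0.push_back(bp(r, 0)); e.b_k.push_back(bp(r, 1));
  }
  IntegerMatrix ai = spec["angles_idx"]; NumericMatrix ap = spec["angles_par"];
  for (int r = 0; r < ai.nrow(); ++r) {
    e.a_i.push_back(ai(r, 0)); e.a_j.push_back(ai(r, 1)); e.a_k.push_back(ai(r, 2));
    e.a_t0.push_back(ap(r, 0)); e.a_kt.push_back(ap(r, 1));
  }
  IntegerMatrix di = spec["dihedrals_idx"]; NumericMatrix dp = spec["dihedrals_par"];
  for (int r = 0; r < di.nrow(); ++r) {
    e.d_i.push_back(di(r, 0)); e.d_j.push_back(di(r, 1));
    e.d_k.push_back(di(r, 2)); e.d_l.push_back(di(r, 3));
    e.d_p0.push_back(dp(r, 0)); e.d_kd.push_back(dp(r, 1));
    e.d_type.push_back((int)dp(r, 2));
  }
  IntegerMatrix ci = spec["contacts_idx"]; NumericMatrix cp = spec["contacts_par"];
  for (int r = 0; r < ci.nrow(); ++r) {
    e.c_i.push_back(ci(r, 0)); e.c_j.push_back(ci(r, 1));
    e.c_rn.push_back(cp(r, 0)); e.c_eps.push_back(cp(r, 1));
  }
  IntegerVector li = spec["link_idx"];
  if (li.size() == 2) {
    NumericVector lp = spec["link_par"];
    e.link_i = li[0]; e.link_j = li[1];
    e.link_r0 = lp[0]; e.link_k = lp[1];
  }
  IntegerMatrix pi = spec["pairs_idx"];
  NumericMatrix pp = spec["pairs_par"];  // cols: inter, aq, heps
  List par = spec["params"];
  e.box      = as<double>(par["box"]);
  e.lambdaD  = as<double>(par["lambda_d"]);
  e.elec_cut = as<double>(par["elec_cutoff"]);
  e.hp_r0    = as<double>(par["hp_r0"]);
  e.hp_C     = as<double>(par["hp_c"]);
  e.hp_cut   = as<double>(par["hp_cutoff"]);
  e.rep_sig  = as<double>(par["rep_sigma"]);
  e.rep_eps  = as<double>(par["rep_eps"]);
  e.rep_cut  = as<double>(par["rep_cutoff"]);
  // energy- and force-shifted truncation: both V and dV/dr reach zero at the
  // cutoff, so finite-difference and analytic forces agree across it
  double sr = e.rep_sig / e.rep_cut;
  e.rep_shift = e.rep_eps * std::pow(sr, 12);
  e.rep_dslope = 12.0 * e.rep_shift / e.rep_cut;
  double exc = std::exp(-e.elec_cut / e.lambdaD);
  e.elec_shift_scale = exc / e.elec_cut;
  e.elec_dslope = exc * (1.0 / (e.elec_cut * e.elec_cut) +
                         1.0 / (e.lambdaD * e.elec_cut));

  for (int r = 0; r < pi.nrow(); ++r) {
    double aq = pp(r, 1), heps = pp(r, 2);
    double cut = e.rep_cut;
    if (aq != 0.0 && e.elec_cut > cut) cut = e.elec_cut;
    if (heps != 0.0 && e.hp_cut > cut) cut = e.hp_cut;
    e.p_i.push_back(pi(r, 0)); e.p_j.push_back(pi(r, 1));
    e.p_inter.push_back((char)pp(r, 0));
    e.p_aq.push_back(aq); e.p_heps.push_back(heps);
    e.p_cut.push_back(cut);
  }
  return e;
}

struct EnergyTerms {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, repulsive = 0,
         link = 0, elec = 0, hp = 0;
  double total() const {
    return bond + angle + dihedral + contact + repulsive + link + elec + hp;
  }
};

static inline void pair_delta(const Engine &e, const double *x, int i, int j,
                              bool inter, double d[3], double &r2) {
  r2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    double dx = x[3 * i + c] - x[3 * j + c];
    if (inter && e.box > 0.0) dx -= e.box * std::nearbyint(dx / e.box);
    d[c] = dx; r2 += dx * dx;
  }
}

// Full energy + forces.  `f` may be nullptr (energy only).  `nb_list` is an
// optional Verlet list of candidate-pair indices; when nullptr all candidate
// pairs are evaluated.
static EnergyTerms eval_all(const Engine &e, const double *x, double *f,
                            const std::vector<int> *nb_list) {
  EnergyTerms E;
  if (f) std::fill(f, f + 3 * e.n, 0.0);

  // bonds (plus the linkage bond, bookkept separately): V = k (r - r0)^2
  size_t nb = e.b_i.size();
  for (size_t t = 0; t <= nb; ++t) {
    int i, j; double r0, k; bool is_link = (t == nb);
    if (is_link) {
      if (e.link_i < 0) break;
      i = e.link_i; j = e.link_j; r0 = e.link_r0; k = e.link_k;
    } else { i = e.b_i[t]; j = e.b_j[t]; r0 = e.b_r0[t]; k = e.b_k[t]; }
    double d[3], r2; pair_delta(e, x, i, j, false, d, r2);
    double r = std::sqrt(r2), dr = r - r0;
    double v = k * dr * dr;
    if (is_link) E.link += v; else E.bond += v;
    if (f) {
      double fac = -2.0 * k * dr / r;
      for (int c = 0; c < 3; ++c) { f[3*i+c] += fac * d[c]; f[3*j+c] -= fac * d[c]; }
    }
  }

  // angles: V = k (theta - theta0)^2
  for (size_t t = 0; t < e.a_i.size(); ++t) {
    int i = e.a_i[t], j = e.a_j[t], k = e.a_k[t];
    double rij[3], rkj[3], r2ij, r2kj;
    pair_delta(e, x, i, j, false, rij, r2ij);
    pair_delta(e, x, k, j, false, rkj, r2kj);
    double nij = std::sqrt(r2ij), nkj = std::sqrt(r2kj);
    double cs = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs), dth = th - e.a_t0[t];
    E.angle += e.a_kt[t] * dth * dth;
    if (f) {
      double sn = std::sqrt(std::max(1e-12, 1.0 - cs * cs));
      double dVdth = 2.0 * e.a_kt[t] * dth;
      for (int c = 0; c < 3; ++c) {
        double ui = rij[c] / nij, uk = rkj[c] / nkj;
        double fi = dVdth / (nij * sn) * (uk - cs * ui);
        double fk = dVdth / (nkj * sn) * (ui - cs * uk);
        f[3*i+c] += fi; f[3*k+c] += fk; f[3*j+c] -= (fi + fk);
      }
    }
  }

  // dihedrals: type 1 -> k[(1-cos(dphi)) + 0.5 (1-cos(3 dphi))]; type 2 -> k(1-cos(dphi))
  for (size_t t = 0; t < e.d_i.size(); ++t) {
    int i = e.d_i[t], j = e.d_j[t], k = e.d_k[t], l = e.d_l[t];
    double b1[3], b2[3], b3[3], r2;
    pair_delta(e, x, j, i, false, b1, r2);
    pair_delta(e, x, k, j, false, b2, r2);
    pair_delta(e, x, l, k, false, b3, r2);
    double m[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
    double nn[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
    double b2n = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    double xx = m[0]*nn[0] + m[1]*nn[1] + m[2]*nn[2];
    double yy = b2n * (b1[0]*nn[0] + b1[1]*nn[1] + b1[2]*nn[2]);
    double phi = std::atan2(yy, xx);
    double dphi = phi - e.d_p0[t];
    double kd = e.d_kd[t], V, dVdphi;
    if (e.d_type[t] == 1) {
      V = kd * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
      dVdphi = kd * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
    } else {
      V = kd * (1.0 - std::cos(dphi));
      dVdphi = kd * std::sin(dphi);
    }
    E.dihedral += V;
    if (f) {
      double m2 = m[0]*m[0] + m[1]*m[1] + m[2]*m[2];
      double n2 = nn[0]*nn[0] + nn[1]*nn[1] + nn[2]*nn[2];
      if (m2 > 1e-12 && n2 > 1e-12) {
        double s = (b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2]) / (b2n * b2n);
        double tt = (b3[0]*b2[0] + b3[1]*b2[1] + b3[2]*b2[2]) / (b2n * b2n);
        for (int c = 0; c < 3; ++c) {
          double fi =  dVdphi * b2n / m2 * m[c];
          double fl = -dVdphi * b2n / n2 * nn[c];
          double fj = -(1.0 + s) * fi + tt * fl;
          double fk = -(fi + fj + fl);
          f[3*i+c] += fi; f[3*j+c] += fj; f[3*k+c] += fk; f[3*l+c] += fl;
        }
      }
    }
  }

  // native contacts: 12-10, V = eps (5 (rn/r)^12 - 6 (rn/r)^10)
  for (size_t t = 0; t < e.c_i.size(); ++t) {
    int i = e.c_i[t], j = e.c_j[t];
    double d[3], r2; pair_delta(e, x, i, j, false, d, r2);
    double r = std::sqrt(r2), xr = e.c_rn[t] / r;
    double x2 = xr * xr, x4 = x2 * x2, x10 = x4 * x4 * x2, x12 = x10 * x2;
    E.contact += e.c_eps[t] * (5.0 * x12 - 6.0 * x10);
    if (f) {
      double dVdr = -60.0 * e.c_eps[t] * (x12 - x10) / r;
      double fac = -dVdr / r;
      for (int c = 0; c < 3; ++c) { f[3*i+c] += fac * d[c]; f[3*j+c] -= fac * d[c]; }
    }
  }

  // non-bonded candidate pairs: repulsion everywhere, DH/HP where flagged
  size_t np = nb_list ? nb_list->size() : e.p_i.size();
  for (size_t tt = 0; tt < np; ++tt) {
    size_t t = nb_list ? (size_t)(*nb_list)[tt] : tt;
    int i = e.p_i[t], j = e.p_j[t];
    bool inter = e.p_inter[t] != 0;
    double d[3], r2; pair_delta(e, x, i, j, inter, d, r2);
    if (r2 > e.p_cut[t] * e.p_cut[t]) continue;
    double r = std::sqrt(r2);
    double dVdr = 0.0;

    if (r < e.rep_cut) {
      double sr = e.rep_sig / r;
      double sr2 = sr * sr, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      E.repulsive += e.rep_eps * sr12 - e.rep_shift +
        e.rep_dslope * (r - e.rep_cut);
      dVdr += -12.0 * e.rep_eps * sr12 / r + e.rep_dslope;
    }
    double aq = e.p_aq[t];
    if (aq != 0.0 && r < e.elec_cut) {
      double ex = std::exp(-r / e.lambdaD);
      E.elec += aq * (ex / r - e.elec_shift_scale +
                      e.elec_dslope * (r - e.elec_cut));
      dVdr += aq * (-ex * (1.0 / (r * r) + 1.0 / (e.lambdaD * r)) +
                    e.elec_dslope);
    }
    double heps = e.p_heps[t];
    if (heps != 0.0 && r < e.hp_cut) {
      double th = std::tanh(e.hp_C * (e.hp_r0 - r));
      E.hp += -heps * 0.5 * (1.0 + th);
      dVdr += 0.5 * heps * e.hp_C * (1.0 - th * th);
    }
    if (f && dVdr != 0.0) {
      double fac = -dVdr / r;
      for (int c = 0; c < 3; ++c) { f[3*i+c] += fac * d[c]; f[3*j+c] -= fac * d[c]; }
    }
  }
  return E;
}

static NumericVector terms_to_vector(const EnergyTerms &E) {
  return NumericVector::create(
    _["bond"] = E.bond, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
    _["contact"] = E.contact, _["repulsive"] = E.repulsive, _["link"] = E.link,
    _["elec"] = E.elec, _["hp"] = E.hp, _["total"] = E.total());
}

// [[Rcpp::export(name = ".cg_energy_cpp")]]
NumericVector cg_energy_cpp(List spec, NumericMatrix pos) {
  Engine e = unpack_engine(spec);
  if (pos.nrow() != e.n) stop("position/bead count mismatch");
  std::vector<double> x(3 * e.n);
  for (int i = 0; i < e.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  EnergyTerms E = eval_all(e, x.data(), nullptr, nullptr);
  return terms_to_vector(E);
}

// [[Rcpp::export(name = ".cg_forces_cpp")]]
NumericMatrix cg_forces_cpp(List spec, NumericMatrix pos) {
  Engine e = unpack_engine(spec);
  if (pos.nrow() != e.n) stop("position/bead count mismatch");
  std::vector<double> x(3 * e.n), f(3 * e.n);
  for (int i = 0; i < e.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  eval_all(e, x.data(), f.data(), nullptr);
  NumericMatrix out(e.n, 3);
  for (int i = 0; i < e.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = f[3 * i + c];
  return out;
}

// Verlet-list rebuild: keep candidate pairs within (cut + skin).
static void rebuild_list(const Engine &e, const double *x, double skin,
                         std::vector<int> &list) {
  list.clear();
  for (size_t t = 0; t < e.p_i.size(); ++t) {
    double d[3], r2;
    pair_delta(e, x, e.p_i[t], e.p_j[t], e.p_inter[t] != 0, d, r2);
    double c = e.p_cut[t] + skin;
    if (r2 < c * c) list.push_back((int)t);
  }
}

// [[Rcpp::export(name = ".cg_langevin_cpp")]]
List cg_langevin_cpp(List spec, NumericMatrix pos, NumericMatrix vel,
                     double dt, double gamma, double kT, double mass,
                     int nsteps, int stride, CharacterVector rng_state) {
  Engine e = unpack_engine(spec);
  int n = e.n;
  if (pos.nrow() != n || vel.nrow() != n) stop("position/velocity bead count mismatch");
  Xoshiro rng; rng_state_from_hex(rng, rng_state);

  std::vector<double> x(3 * n), v(3 * n), f(3 * n), x0(3 * n), xref(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { x[3*i+c] = pos(i, c); v[3*i+c] = vel(i, c); }

  const double skin = 0.3;
  std::vector<int> nb_list;
  rebuild_list(e, x.data(), skin, nb_list);
  xref = x;

  EnergyTerms E = eval_all(e, x.data(), f.data(), &nb_list);
  double c1 = std::exp(-gamma * dt);
  double c2 = (kT > 0.0) ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;
  double maxmove = (e.box > 0.0) ? 0.5 * e.box : 2.0;

  int nframes = (stride > 0) ? nsteps / stride : 0;
  NumericVector frames(nframes > 0 ? (R_xlen_t)nframes * n * 3 : 0);
  NumericVector epot(nframes), ekin(nframes), ftime(nframes);
  int fidx = 0;
  bool diverged = false;
  int diverged_step = -1;

  // cached normal draw for Box-Muller; reset each step so that chunked runs
  // concatenate bit-identically at step boundaries
  for (int step = 1; step <= nsteps; ++step) {
    x0 = x;
    // B: half kick
    double hdtm = 0.5 * dt / mass;
    for (int i = 0; i < 3 * n; ++i) v[i] += hdtm * f[i];
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: friction + noise (Box-Muller pairs, spare draw discarded)
    if (kT > 0.0) {
      int nrand = 3 * n;
      int i = 0;
      while (i < nrand) {
        double u1 = rng.unif(), u2 = rng.unif();
        double rr = std::sqrt(-2.0 * std::log(u1));
        double z1 = rr * std::cos(2.0 * M_PI * u2);
        double z2 = rr * std::sin(2.0 * M_PI * u2);
        v[i] = c1 * v[i] + c2 * z1; ++i;
        if (i < nrand) { v[i] = c1 * v[i] + c2 * z2; ++i; }
      }
    } else {
      for (int i = 0; i < 3 * n; ++i) v[i] *= c1;
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    // divergence + Verlet-list displacement bookkeeping
    double maxdisp_step = 0.0, maxdisp_ref = 0.0;
    for (int i = 0; i < n; ++i) {
      double ds = 0.0, dr = 0.0;
      for (int c = 0; c < 3; ++c) {
        double a = x[3*i+c] - x0[3*i+c]; ds += a * a;
        double b = x[3*i+c] - xref[3*i+c]; dr += b * b;
      }
      if (ds > maxdisp_step) maxdisp_step = ds;
      if (dr > maxdisp_ref) maxdisp_ref = dr;
    }
    if (std::sqrt(maxdisp_step) > maxmove || !std::isfinite(maxdisp_step)) {
      diverged = true; diverged_step = step; break;
    }
    if (2.0 * std::sqrt(maxdisp_ref) > skin) {
      rebuild_list(e, x.data(), skin, nb_list);
      xref = x;
    }

    // B: half kick with new forces
    E = eval_all(e, x.data(), f.data(), &nb_list);
    for (int i = 0; i < 3 * n; ++i) v[i] += hdtm * f[i];

    if (stride > 0 && step % stride == 0 && fidx < nframes) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[(R_xlen_t)fidx * 3 * n + (R_xlen_t)c * n + i] = x[3*i+c];
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * mass * v[i] * v[i];
      epot[fidx] = E.total(); ekin[fidx] = ke; ftime[fidx] = step * dt;
      ++fidx;
    }
  }

  NumericMatrix outx(n, 3), outv(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { outx(i, c) = x[3*i+c]; outv(i, c) = v[3*i+c]; }
  if (nframes > 0) frames.attr("dim") = IntegerVector::create(n, 3, nframes);

  return List::create(
    _["frames"] = frames, _["time"] = ftime,
    _["epot"] = epot, _["ekin"] = ekin,
    _["pos"] = outx, _["vel"] = outv,
    _["rng_state"] = rng_state_to_hex(rng),
    _["diverged"] = diverged, _["diverged_step"] = diverged_step,
    _["nframes"] = fidx);
}

// Per-frame energy decomposition over a whole trajectory.
// frames: [n, 3, F] -> matrix F x 9 (bond, angle, dihedral, contact,
// repulsive, link, elec, hp, total)
// [[Rcpp::export(name = ".cg_energy_frames_cpp")]]
NumericMatrix cg_energy_frames_cpp(List spec, NumericVector frames) {
  Engine e = unpack_engine(spec);
  IntegerVector dim = frames.attr("dim");
  if (dim[0] != e.n) stop("frame/bead count mismatch");
  int n = e.n, F = dim[2];
  NumericMatrix out(F, 9);
  colnames(out) = CharacterVector::create("bond", "angle", "dihedral",
    "contact", "repulsive", "link", "elec", "hp", "total");
  std::vector<double> x(3 * n);
  for (int fr = 0; fr < F; ++fr) {
    const double *X = &frames[(R_xlen_t)fr * 3 * n];
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) x[3 * i + c] = X[c * n + i];
    EnergyTerms E = eval_all(e, x.data(), nullptr, nullptr);
    out(fr, 0) = E.bond; out(fr, 1) = E.angle; out(fr, 2) = E.dihedral;
    out(fr, 3) = E.contact; out(fr, 4) = E.repulsive; out(fr, 5) = E.link;
    out(fr, 6) = E.elec; out(fr, 7) = E.hp; out(fr, 8) = E.total();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Interfacial contact counting across frames (analysis helper).
// ---------------------------------------------------------------------------
// frames: [n, 3, F]; mono: 1/2 per bead; resid: residue index per bead (1-based)
// Counts inter-monomer bead pairs within `cutoff` for frames whose
// (minimum-image) centre-of-mass distance is <= dcom_max.
// [[Rcpp::export(name = ".count_inter_contacts_cpp")]]
List count_inter_contacts_cpp(NumericVector frames, IntegerVector mono,
                              IntegerVector resid, int nres, double cutoff,
                              double box, double dcom_max) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], F = dim[2];
  std::vector<int> idx1, idx2;
  for (int i = 0; i < n; ++i) (mono[i] == 1 ? idx1 : idx2).push_back(i);

  NumericVector prof1(nres), prof2(nres);
  NumericMatrix mat(nres, nres);
  int used = 0;
  double cut2 = cutoff * cutoff;

  for (int fr = 0; fr < F; ++fr) {
    const double *X = &frames[(R_xlen_t)fr * 3 * n];
    // centre of mass of each monomer (equal weights, unwrapped)
    double com1[3] = {0,0,0}, com2[3] = {0,0,0};
    for (int c = 0; c < 3; ++c) {
      for (size_t t = 0; t < idx1.size(); ++t) com1[c] += X[c * n + idx1[t]];
      for (size_t t = 0; t < idx2.size(); ++t) com2[c] += X[c * n + idx2[t]];
      com1[c] /= idx1.size(); com2[c] /= idx2.size();
    }
    double d2 = 0.0, shift[3];
    for (int c = 0; c < 3; ++c) {
      double dx = com1[c] - com2[c];
      double w = (box > 0.0) ? box * std::nearbyint(dx / box) : 0.0;
      shift[c] = w; dx -= w; d2 += dx * dx;
    }
    if (std::sqrt(d2) > dcom_max) continue;
    ++used;
    for (size_t a = 0; a < idx1.size(); ++a) {
      int i = idx1[a];
      for (size_t b = 0; b < idx2.size(); ++b) {
        int j = idx2[b];
        double r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          // apply the same image shift as the COM separation
          double dx = X[c * n + i] - (X[c * n + j] + shift[c]);
          r2 += dx * dx;
        }
        if (r2 < cut2) {
          prof1[resid[i] - 1] += 1.0;
          prof2[resid[j] - 1] += 1.0;
          mat(resid[i] - 1, resid[j] - 1) += 1.0;
        }
      }
    }
  }
  if (used > 0) {
    for (int r = 0; r < nres; ++r) { prof1[r] /= used; prof2[r] /= used; }
    for (int r = 0; r < nres; ++r)
      for (int s = 0; s < nres; ++s) mat(r, s) /= used;
  }
  return List::create(_["profile1"] = prof1, _["profile2"] = prof2,
                      _["matrix"] = mat, _["frames_used"] = used);
}
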