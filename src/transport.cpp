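// Single-interaction Monte Carlo transport core.
//
// Primary ions alternate CSDA substeps (Bethe stopping power, optional
// Bohr straggling, optional delta-ray conversion) with discrete elastic
// collisions sampled from the screened Rutherford cross section above a
// cutoff angle theta_min. Delta electrons use a practical-range model:
// straight emission direction from binary-encounter kinematics, an
// exponential detour factor for path tortuosity, and uniform energy
// deposition along the straight segment.
//
// Each primary owns three named random sub-streams (elastic, straggling,
// delta), seeded from (master seed, primary id, stream tag), so toggling
// one physics process does not perturb the others' sequences and results
// are independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ----------------------------------------------------------------------
// constants (must match R/constants.R)
static const double ME_C2   = 0.51099895;     // MeV
static const double K_BETHE = 0.307075;       // MeV cm^2 / mol
static const double N_AVO   = 6.02214076e23;
static const double HBAR_C  = 197.3269804;    // MeV fm
static const double E2      = 1.43996454;     // MeV fm
static const double A0_FM   = 52917.72109;
static const double FM2_CM2 = 1e-26;

// ----------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256**
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  double spare; bool has_spare;
  void seed(uint64_t master, uint64_t id, uint64_t stream) {
    uint64_t x = master * 0x9E3779B97F4A7C15ULL
               ^ (id + 1)     * 0xBF58476D1CE4E5B9ULL
               ^ (stream + 1) * 0x94D049BB133111EBULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false; spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expdev() { return -std::log(unif()); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
  int poisson(double mu) { // Knuth; mu is small in practice
    if (mu <= 0) return 0;
    double L = std::exp(-mu), p = 1.0; int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// ----------------------------------------------------------------------
// physics
struct SpeciesC { double z, mass_number, rest_mass, n_u; };
struct MaterialC { double Z, A, density, I_mev, n_atoms; };

struct Kin { double beta, beta2, gamma, pc; };
static inline Kin kinematics(double T_per_u, const SpeciesC &sp) {
  double m_u = sp.mass_number > 0 ? sp.rest_mass / sp.mass_number : sp.rest_mass;
  Kin k;
  k.gamma = 1.0 + T_per_u / m_u;
  k.beta2 = 1.0 - 1.0 / (k.gamma * k.gamma);
  k.beta  = std::sqrt(k.beta2);
  k.pc    = k.gamma * k.beta * m_u * sp.n_u;
  return k;
}

static inline double tmax_mev(const Kin &k, const SpeciesC &sp) {
  double r = ME_C2 / sp.rest_mass;
  return 2.0 * ME_C2 * k.beta2 * k.gamma * k.gamma /
         (1.0 + 2.0 * k.gamma * r + r * r);
}

static inline double stop_power(double T_per_u, const SpeciesC &sp,
                                const MaterialC &mat) { // MeV/cm
  Kin k = kinematics(T_per_u, sp);
  double tmax = tmax_mev(k, sp);
  double arg = 2.0 * ME_C2 * k.beta2 * k.gamma * k.gamma * tmax /
               (mat.I_mev * mat.I_mev);
  return K_BETHE * sp.z * sp.z * (mat.Z / mat.A) * mat.density / k.beta2 *
         (0.5 * std::log(arg) - k.beta2);
}

static inline double screening_eta(const Kin &k, const MaterialC &mat) {
  double a_tf = 0.885 * A0_FM * std::pow(mat.Z, -1.0 / 3.0);
  double x = HBAR_C / (k.pc * a_tf);
  return 0.25 * x * x;
}

// sigma(theta > theta_min), cm^2
static inline double sigma_above(const Kin &k, const SpeciesC &sp,
                                 const MaterialC &mat, double tmin_1mc,
                                 double eta) {
  double C_fm = sp.z * mat.Z * E2 / (k.pc * k.beta);
  double C2 = C_fm * C_fm * FM2_CM2;
  return 2.0 * M_PI * C2 * (1.0 / (tmin_1mc + 2.0 * eta) - 1.0 / (2.0 + 2.0 * eta));
}

// inverse CDF of the full screened Rutherford angular distribution
static inline double sample_1mcos(double u, double eta) {
  return 2.0 * eta * u / (1.0 + eta - u);
}

// rotate unit vector d by polar angle theta (cos ct, sin st) and azimuth phi
static inline void rotate_dir(double *d, double ct, double st, double phi) {
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double den2 = 1.0 - uz * uz;
  if (den2 < 1e-20) {
    double sgn = uz >= 0 ? 1.0 : -1.0;
    d[0] = st * cp; d[1] = sgn * st * sp; d[2] = sgn * ct;
  } else {
    double den = std::sqrt(den2);
    d[0] = ux * ct + st * (ux * uz * cp - uy * sp) / den;
    d[1] = uy * ct + st * (uy * uz * cp + ux * sp) / den;
    d[2] = uz * ct - den * st * cp;
  }
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

// ----------------------------------------------------------------------
// tallies / output buffers
struct Tally {
  bool store;
  double store_zmin, store_zmax;
  bool use_sphere;
  double sx, sy, sz, sr2;
  bool depth_on;
  double depth_z0, depth_dz; int depth_n;
  std::vector<double> depth;

  std::vector<int> dep_id;
  std::vector<double> dep_x, dep_y, dep_z, dep_amt;
  std::vector<int> dep_src;

  double ledger_dep; // MeV, current track

  void add(int id, double x, double y, double z, double amt_kev, int src) {
    if (amt_kev <= 0) return;
    ledger_dep += amt_kev * 1e-3;
    if (depth_on) {
      int b = (int)std::floor((z - depth_z0) / depth_dz);
      if (b >= 0 && b < depth_n) depth[b] += amt_kev;
    }
    if (!store) return;
    if (z < store_zmin || z > store_zmax) return;
    if (use_sphere) {
      double dx = x - sx, dy = y - sy, dz = z - sz;
      if (dx * dx + dy * dy + dz * dz > sr2) return;
    }
    dep_id.push_back(id);
    dep_x.push_back(x); dep_y.push_back(y); dep_z.push_back(z);
    dep_amt.push_back(amt_kev); dep_src.push_back(src);
  }
};

struct PhysC {
  bool elastic_on;
  double theta_min, tmin_1mc;
  double tcut_kev;
  double substep_fraction, max_substep, min_substep;
  bool straggling_on;
  bool delta_transport;
  double delta_zmin, delta_zmax;
  double floor_mev_u;
  double delta_spacing, delta_detour_mean;
  int delta_max_points;
  bool fine_on;
  double fine_zmin, fine_zmax, fine_cap;
};

struct RangeTab {
  std::vector<double> logT, R;
  double logT0, dlog; int n;
  double operator()(double T) const { // residual range, cm
    double lt = std::log(T);
    double f = (lt - logT0) / dlog;
    if (f <= 0) return 0.0;
    if (f >= n - 1) f = n - 1 - 1e-9;
    int i = (int)f;
    double w = f - i;
    return R[i] * (1 - w) + R[i + 1] * w;
  }
};

// simplified electron model: practical range in g/cm^2
static inline double electron_range_gcm2(double E_kev) {
  return 4.0e-6 * std::pow(E_kev, 1.75);
}

static void deposit_electron(int id, const double *org, const double *dir,
                             double E_kev, const MaterialC &mat,
                             const PhysC &ph, Rng &rng, Tally &tl) {
  double R = electron_range_gcm2(E_kev) / mat.density; // cm
  double det = ph.delta_detour_mean * rng.expdev();
  if (det > 1.0) det = 1.0;
  double L = R * det;
  int n = (int)std::ceil(L / ph.delta_spacing);
  if (n < 4) n = 4;
  if (n > ph.delta_max_points) n = ph.delta_max_points;
  double e_pt = E_kev / n;
  for (int j = 0; j < n; ++j) {
    double s = (j + rng.unif()) / n * L;
    tl.add(id, org[0] + s * dir[0], org[1] + s * dir[1], org[2] + s * dir[2],
           e_pt, 1);
  }
}

struct ExitRec {
  bool exited;
  double x, y, z, dx, dy, dz, T_per_u;
  int n_elastic;
  double E_in, E_dep, E_exit;
};

struct SecBuf {
  bool on;
  std::vector<int> id;
  std::vector<double> x, y, z, dx, dy, dz, E_kev;
};

// transport one primary ion through a slab/box; returns exit record
static ExitRec transport_one(int id, const double *pos0, const double *dir0,
                             double T0_per_u, const SpeciesC &sp,
                             const MaterialC &mat, double thickness,
                             double half_x, double half_y,
                             const PhysC &ph, const RangeTab &rt,
                             uint64_t master, Tally &tl, SecBuf &sec) {
  Rng rng_el, rng_st, rng_dl;
  rng_el.seed(master, (uint64_t)id, 1);
  rng_st.seed(master, (uint64_t)id, 2);
  rng_dl.seed(master, (uint64_t)id, 3);

  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  double T = T0_per_u;            // MeV/u
  double E = T * sp.n_u;          // MeV total kinetic
  ExitRec ex; ex.exited = false; ex.n_elastic = 0;
  ex.E_in = E; tl.ledger_dep = 0.0;

  double tau = ph.elastic_on ? rng_el.expdev() : 0.0; // collision depth in mfp units
  double T_cache = -1.0, sp_cache = 0.0, eta_cache = 0.0, mfp_cache = INFINITY;
  Kin k_cache;
  const int max_iter = 50000000;
  for (int iter = 0; iter < max_iter; ++iter) {
    if (T <= ph.floor_mev_u) { // terminate: deposit residual energy locally
      tl.add(id, pos[0], pos[1], pos[2], E * 1e3, 0);
      E = 0.0;
      break;
    }
    // geometric distance to boundary
    double s_geom = INFINITY;
    if (dir[2] > 1e-12)       s_geom = (thickness - pos[2]) / dir[2];
    else if (dir[2] < -1e-12) s_geom = -pos[2] / dir[2];
    if (std::isfinite(half_x)) {
      if (dir[0] > 1e-12)       s_geom = std::min(s_geom, ( half_x - pos[0]) / dir[0]);
      else if (dir[0] < -1e-12) s_geom = std::min(s_geom, (-half_x - pos[0]) / dir[0]);
      if (dir[1] > 1e-12)       s_geom = std::min(s_geom, ( half_y - pos[1]) / dir[1]);
      else if (dir[1] < -1e-12) s_geom = std::min(s_geom, (-half_y - pos[1]) / dir[1]);
    }
    if (s_geom <= 0) { ex.exited = true; break; } // already on the way out

    // substep length
    double resid = rt(T);
    double cap = ph.max_substep;
    if (ph.fine_on && pos[2] >= ph.fine_zmin - cap && pos[2] <= ph.fine_zmax)
      cap = std::min(cap, ph.fine_cap);
    double s_sub = ph.substep_fraction * resid;
    if (s_sub > cap) s_sub = cap;
    if (s_sub < ph.min_substep) s_sub = ph.min_substep;

    // energy-dependent physics, cached while T changes by < 1e-4 relative
    // (collisions between substeps do not change T)
    if (T_cache <= 0 || std::fabs(T - T_cache) > 1e-4 * T_cache) {
      k_cache = kinematics(T, sp);
      sp_cache = stop_power(T, sp, mat);
      if (ph.elastic_on) {
        eta_cache = screening_eta(k_cache, mat);
        double sig = sigma_above(k_cache, sp, mat, ph.tmin_1mc, eta_cache);
        mfp_cache = 1.0 / (mat.n_atoms * sig);
      }
      T_cache = T;
    }
    const Kin &k = k_cache;
    double eta = eta_cache, mfp = mfp_cache, s_coll = INFINITY;
    if (ph.elastic_on) s_coll = tau * mfp;

    double s = std::min(std::min(s_sub, s_geom), s_coll);
    int kind = (s == s_geom) ? 0 : (s == s_coll ? 2 : 1);

    // Energy loss over s. Where delta rays are explicitly produced, the
    // continuous part is the restricted stopping power (transfers below
    // Tcut) and each delta is a discrete loss; elsewhere the full Bethe
    // loss is continuous. The sampled 1/T^2 spectrum has mean
    // mu<Td> = C' ln(Tmax/Tcut) per path, so the restricted bracket is
    // 0.5 ln(2 m beta^2 gamma^2 Tcut / I^2) - beta^2 and the split is
    // consistent with the total in expectation.
    bool in_delta_win = ph.delta_transport &&
                        pos[2] >= ph.delta_zmin && pos[2] <= ph.delta_zmax;
    double tmax_kev = tmax_mev(k, sp) * 1e3;
    bool discrete_deltas = in_delta_win && tmax_kev > ph.tcut_kev;

    double sum_del = 0.0;
    if (discrete_deltas) {
      double mu = 0.5 * K_BETHE * sp.z * sp.z * (mat.Z / mat.A) *
                  mat.density / k.beta2 *
                  (1.0 / (ph.tcut_kev * 1e-3) - 1.0 / (tmax_kev * 1e-3)) * s;
      int nd = rng_dl.poisson(mu);
      for (int j = 0; j < nd; ++j) {
        double Td = ph.tcut_kev * tmax_kev /
                    (tmax_kev - rng_dl.unif() * (tmax_kev - ph.tcut_kev));
        if ((sum_del + Td) * 1e-3 > E - ph.floor_mev_u * sp.n_u) break;
        sum_del += Td;
        double su = rng_dl.unif() * s;
        double org[3] = {pos[0] + su * dir[0], pos[1] + su * dir[1],
                         pos[2] + su * dir[2]};
        double ddir[3] = {dir[0], dir[1], dir[2]};
        double cth = std::sqrt(Td / tmax_kev);
        rotate_dir(ddir, cth, std::sqrt(1.0 - cth * cth),
                   6.283185307179586 * rng_dl.unif());
        if (sec.on) {
          sec.id.push_back(id);
          sec.x.push_back(org[0]); sec.y.push_back(org[1]); sec.z.push_back(org[2]);
          sec.dx.push_back(ddir[0]); sec.dy.push_back(ddir[1]); sec.dz.push_back(ddir[2]);
          sec.E_kev.push_back(Td);
        }
        deposit_electron(id, org, ddir, Td, mat, ph, rng_dl, tl);
      }
    }

    double dE_cont;
    if (discrete_deltas) {
      double arg_r = 2.0 * ME_C2 * k.beta2 * k.gamma * k.gamma *
                     (ph.tcut_kev * 1e-3) / (mat.I_mev * mat.I_mev);
      double br = 0.5 * std::log(arg_r) - k.beta2;
      if (br < 0.05) br = 0.05; // guard near the validity floor
      dE_cont = K_BETHE * sp.z * sp.z * (mat.Z / mat.A) * mat.density /
                k.beta2 * br * s;
    } else {
      dE_cont = sp_cache * s;
    }
    if (ph.straggling_on) {
      double var = K_BETHE * ME_C2 * sp.z * sp.z * (mat.Z / mat.A) *
                   mat.density * s;
      // with discrete deltas above Tcut, only sub-Tcut transfers straggle
      if (discrete_deltas) var *= ph.tcut_kev / tmax_kev;
      dE_cont += std::sqrt(var) * rng_st.norm();
      if (dE_cont < 0) dE_cont = 0;
    }
    bool dies = false;
    double dE = dE_cont + sum_del * 1e-3; // MeV
    if (dE >= E || (E - dE) / sp.n_u <= ph.floor_mev_u) {
      dE_cont = E - sum_del * 1e-3; // deposit the rest locally and stop
      dE = E;
      dies = true;
    }
    // continuous (restricted) deposit at a jittered point along the step
    double su = rng_st.unif() * s;
    tl.add(id, pos[0] + su * dir[0], pos[1] + su * dir[1], pos[2] + su * dir[2],
           dE_cont * 1e3, 0);

    pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
    E -= dE; T = E / sp.n_u;
    if (dies) { E = 0.0; break; }

    if (kind == 0) { ex.exited = true; break; }
    if (kind == 2) {
      // discrete elastic collision, angle conditioned on theta > theta_min
      double u_min = (1.0 + eta) * ph.tmin_1mc / (ph.tmin_1mc + 2.0 * eta);
      double u = u_min + rng_el.unif() * (1.0 - u_min);
      double omc = sample_1mcos(u, eta);
      double ct = 1.0 - omc;
      if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
      rotate_dir(dir, ct, std::sqrt(std::max(0.0, 1.0 - ct * ct)),
                 6.283185307179586 * rng_el.unif());
      ex.n_elastic++;
      tau = rng_el.expdev();
    } else if (ph.elastic_on) {
      tau -= s / mfp;
      if (tau <= 0) tau = 1e-12; // numerical guard; collision next step
    }
  }

  ex.x = pos[0]; ex.y = pos[1]; ex.z = pos[2];
  ex.dx = dir[0]; ex.dy = dir[1]; ex.dz = dir[2];
  ex.T_per_u = ex.exited ? T : 0.0;
  ex.E_exit = ex.exited ? E : 0.0;
  ex.E_dep = tl.ledger_dep;
  return ex;
}

// ----------------------------------------------------------------------
static SpeciesC as_species(List s) {
  SpeciesC sp;
  sp.z = as<double>(s["z"]);
  sp.mass_number = as<double>(s["mass_number"]);
  sp.rest_mass = as<double>(s["rest_mass"]);
  sp.n_u = sp.mass_number > 0 ? sp.mass_number : 1.0;
  return sp;
}
static MaterialC as_material(List m) {
  MaterialC mat;
  mat.Z = as<double>(m["Z"]); mat.A = as<double>(m["A"]);
  mat.density = as<double>(m["density"]);
  mat.I_mev = as<double>(m["I"]) * 1e-6;
  mat.n_atoms = mat.density * N_AVO / mat.A;
  return mat;
}
static PhysC as_phys(List p) {
  PhysC ph;
  ph.elastic_on = as<bool>(p["elastic_on"]);
  ph.theta_min = as<double>(p["theta_min"]);
  ph.tmin_1mc = 1.0 - std::cos(ph.theta_min);
  ph.tcut_kev = as<double>(p["tcut_kev"]);
  ph.substep_fraction = as<double>(p["substep_fraction"]);
  ph.max_substep = as<double>(p["max_substep_cm"]);
  ph.min_substep = as<double>(p["min_substep_cm"]);
  ph.straggling_on = as<bool>(p["straggling_on"]);
  ph.delta_transport = as<bool>(p["delta_transport"]);
  NumericVector dw = p["delta_window"];
  ph.delta_zmin = dw[0]; ph.delta_zmax = dw[1];
  ph.floor_mev_u = as<double>(p["floor_mev_u"]);
  ph.delta_spacing = as<double>(p["delta_point_spacing_cm"]);
  ph.delta_detour_mean = as<double>(p["delta_detour_mean"]);
  ph.delta_max_points = as<int>(p["delta_max_points"]);
  NumericVector fw = p["fine_window"];
  ph.fine_on = fw.size() == 3 && R_finite(fw[0]);
  if (ph.fine_on) { ph.fine_zmin = fw[0]; ph.fine_zmax = fw[1]; ph.fine_cap = fw[2]; }
  else { ph.fine_zmin = ph.fine_zmax = ph.fine_cap = 0.0; }
  return ph;
}

// [[Rcpp::export]]
List run_beam_cpp(int n_primaries, double seed, List species_, List material_,
                  List geometry_, List physics_, List scoring_,
                  NumericVector rt_T, NumericVector rt_R,
                  NumericMatrix init_states) {
  SpeciesC sp = as_species(species_);
  MaterialC mat = as_material(material_);
  PhysC ph = as_phys(physics_);
  double thickness = as<double>(geometry_["thickness"]);
  double half_x = as<double>(geometry_["half_x"]);
  double half_y = as<double>(geometry_["half_y"]);
  double T0 = as<double>(geometry_["T_per_u"]); // beam energy per nucleon

  RangeTab rt;
  rt.n = rt_T.size();
  rt.logT.resize(rt.n); rt.R.resize(rt.n);
  for (int i = 0; i < rt.n; ++i) { rt.logT[i] = std::log(rt_T[i]); rt.R[i] = rt_R[i]; }
  rt.logT0 = rt.logT[0];
  rt.dlog = (rt.logT[rt.n - 1] - rt.logT[0]) / (rt.n - 1);

  Tally tl;
  tl.store = as<bool>(scoring_["store_deposits"]);
  NumericVector zl = scoring_["store_zlim"];
  tl.store_zmin = zl[0]; tl.store_zmax = zl[1];
  NumericVector sphere = scoring_["store_sphere"];
  tl.use_sphere = sphere.size() == 4;
  if (tl.use_sphere) {
    tl.sx = sphere[0]; tl.sy = sphere[1]; tl.sz = sphere[2];
    tl.sr2 = sphere[3] * sphere[3];
  }
  NumericVector de = scoring_["depth_edges"];
  tl.depth_on = de.size() == 3;
  if (tl.depth_on) {
    tl.depth_z0 = de[0]; tl.depth_dz = de[1]; tl.depth_n = (int)de[2];
    tl.depth.assign(tl.depth_n, 0.0);
  } else tl.depth_n = 0;
  tl.ledger_dep = 0.0;

  SecBuf sec; sec.on = as<bool>(scoring_["record_secondaries"]);

  bool custom_init = init_states.nrow() == n_primaries && init_states.ncol() == 7;
  uint64_t master = (uint64_t)seed;

  std::vector<int> ex_id(n_primaries);
  std::vector<int> ex_flag(n_primaries), ex_ncoll(n_primaries);
  std::vector<double> ex_x(n_primaries), ex_y(n_primaries), ex_z(n_primaries),
      ex_dx(n_primaries), ex_dy(n_primaries), ex_dz(n_primaries),
      ex_T(n_primaries), lg_in(n_primaries), lg_dep(n_primaries),
      lg_out(n_primaries);

  for (int i = 0; i < n_primaries; ++i) {
    double pos0[3] = {0, 0, 0}, dir0[3] = {0, 0, 1};
    double Ti = T0;
    if (custom_init) {
      pos0[0] = init_states(i, 0); pos0[1] = init_states(i, 1); pos0[2] = init_states(i, 2);
      dir0[0] = init_states(i, 3); dir0[1] = init_states(i, 4); dir0[2] = init_states(i, 5);
      double nrm = std::sqrt(dir0[0]*dir0[0] + dir0[1]*dir0[1] + dir0[2]*dir0[2]);
      if (std::fabs(nrm - 1.0) > 1e-9) stop("initial direction must be a unit vector");
      Ti = init_states(i, 6);
    }
    ExitRec ex = transport_one(i + 1, pos0, dir0, Ti, sp, mat, thickness,
                               half_x, half_y, ph, rt, master, tl, sec);
    ex_id[i] = i + 1;
    ex_flag[i] = ex.exited ? 1 : 0;
    ex_x[i] = ex.x; ex_y[i] = ex.y; ex_z[i] = ex.z;
    ex_dx[i] = ex.dx; ex_dy[i] = ex.dy; ex_dz[i] = ex.dz;
    ex_T[i] = ex.T_per_u; ex_ncoll[i] = ex.n_elastic;
    lg_in[i] = ex.E_in; lg_dep[i] = ex.E_dep; lg_out[i] = ex.E_exit;
  }

  List out = List::create(
    _["deposits"] = DataFrame::create(
      _["event_id"] = wrap(tl.dep_id), _["x"] = wrap(tl.dep_x),
      _["y"] = wrap(tl.dep_y), _["z"] = wrap(tl.dep_z),
      _["amount"] = wrap(tl.dep_amt), _["source"] = wrap(tl.dep_src)),
    _["exits"] = DataFrame::create(
      _["event_id"] = wrap(ex_id), _["exited"] = wrap(ex_flag),
      _["x"] = wrap(ex_x), _["y"] = wrap(ex_y), _["z"] = wrap(ex_z),
      _["dx"] = wrap(ex_dx), _["dy"] = wrap(ex_dy), _["dz"] = wrap(ex_dz),
      _["T_per_u"] = wrap(ex_T), _["n_elastic"] = wrap(ex_ncoll)),
    _["ledger"] = DataFrame::create(
      _["event_id"] = wrap(ex_id), _["E_in"] = wrap(lg_in),
      _["E_dep"] = wrap(lg_dep), _["E_exit"] = wrap(lg_out)),
    _["depth_kev"] = wrap(tl.depth));
  if (sec.on) {
    out["secondaries"] = DataFrame::create(
      _["event_id"] = wrap(sec.id), _["x"] = wrap(sec.x), _["y"] = wrap(sec.y),
      _["z"] = wrap(sec.z), _["dx"] = wrap(sec.dx), _["dy"] = wrap(sec.dy),
      _["dz"] = wrap(sec.dz), _["energy_kev"] = wrap(sec.E_kev));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stopping_power(NumericVector T_per_u, List species_, List material_) {
  SpeciesC sp = as_species(species_);
  MaterialC mat = as_material(material_);
  NumericVector out(T_per_u.size());
  for (int i = 0; i < T_per_u.size(); ++i) out[i] = stop_power(T_per_u[i], sp, mat);
  return out;
}

// standalone electron transport (simplified model); returns deposit table
// [[Rcpp::export]]
DataFrame cpp_electron_deposits(double E_kev, NumericVector origin,
                                NumericVector direction, List material_,
                                double detour_mean, double point_spacing_cm,
                                int max_points, double seed) {
  MaterialC mat = as_material(material_);
  PhysC ph; ph.delta_detour_mean = detour_mean;
  ph.delta_spacing = point_spacing_cm; ph.delta_max_points = max_points;
  Tally tl; tl.store = true; tl.store_zmin = -INFINITY; tl.store_zmax = INFINITY;
  tl.use_sphere = false; tl.depth_on = false; tl.ledger_dep = 0.0;
  Rng rng; rng.seed((uint64_t)seed, 0, 4);
  double org[3] = {origin[0], origin[1], origin[2]};
  double dir[3] = {direction[0], direction[1], direction[2]};
  deposit_electron(1, org, dir, E_kev, mat, ph, rng, tl);
  return DataFrame::create(
    _["event_id"] = wrap(tl.dep_id), _["x"] = wrap(tl.dep_x),
    _["y"] = wrap(tl.dep_y), _["z"] = wrap(tl.dep_z),
    _["amount"] = wrap(tl.dep_amt), _["source"] = wrap(tl.dep_src));
}
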