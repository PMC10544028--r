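// Coarse-grained condensate engine: nonbonded pair terms (Debye-Hueckel
// electrostatics, 12-6 dispersion for ARO-ARO and optionally ARO-POS,
// r^-12 excluded volume), harmonic bonds/angles, and a BAOAB Langevin
// integrator with a Verlet neighbour list. Units: kcal/mol, Angstrom,
// unit bead mass; the time unit is sqrt(mass A^2 / (kcal/mol)).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// bead classes as passed from R
static const int POS = 1, NEG = 2, ARO = 3, NEU = 4;

struct Model {
  double eps_pipi, eps_catpi;
  bool incl_catpi;
  double sigc, sigr, epsr, kq;
  double r0, kb, th0, kth;
  double rc_disp, rc_elec;          // resolved cutoffs (rc_elec may be huge)
  double kappaD, Bfac, diel;
  // derived
  double rc_rep, rc2_disp, rc2_elec, rc2_rep;
  double shift_pipi, shift_catpi;   // LJ energy at rc_disp per unit eps
  double elec_shift;                // exp(-kd rc)/rc at rc_elec (0 if inf)
};

static Model parse_model(const List& ff) {
  Model m;
  m.eps_pipi = as<double>(ff["eps_pipi"]);
  m.eps_catpi = as<double>(ff["eps_catpi"]);
  m.incl_catpi = as<bool>(ff["include_cation_pi"]);
  m.sigc = as<double>(ff["sigma_contact"]);
  m.sigr = as<double>(ff["sigma_rep"]);
  m.epsr = as<double>(ff["eps_rep"]);
  m.kq = as<double>(ff["k_coulomb"]);
  m.r0 = as<double>(ff["bond_r0"]);
  m.kb = as<double>(ff["bond_k"]);
  m.th0 = as<double>(ff["angle_theta0"]);
  m.kth = as<double>(ff["angle_k"]);
  m.rc_disp = as<double>(ff["cutoff_disp"]);
  m.rc_elec = as<double>(ff["cutoff_elec_resolved"]);
  m.kappaD = as<double>(ff["kappa_d"]);
  m.Bfac = as<double>(ff["debye_b"]);
  m.diel = as<double>(ff["dielectric"]);
  if (!std::isfinite(m.rc_elec) || m.rc_elec > 1e8) m.rc_elec = 1e8;
  m.rc_rep = 2.0 * m.sigr;
  m.rc2_disp = m.rc_disp * m.rc_disp;
  m.rc2_elec = m.rc_elec * m.rc_elec;
  m.rc2_rep = m.rc_rep * m.rc_rep;
  double sr6 = std::pow(m.sigc / m.rc_disp, 6);
  double ulj = sr6 * sr6 - 2.0 * sr6;   // per unit eps
  m.shift_pipi = ulj;
  m.shift_catpi = ulj;
  m.elec_shift = (m.rc_elec < 1e7)
    ? std::exp(-m.kappaD * m.rc_elec) / m.rc_elec : 0.0;
  return m;
}

struct Breakdown {
  double elec = 0, disp = 0, rep = 0, bond = 0, angle = 0;
  double total() const { return elec + disp + rep + bond + angle; }
  void reset() { elec = disp = rep = bond = angle = 0; }
};

static inline double min_image(double d, double box, bool periodic) {
  if (periodic) d -= box * std::nearbyint(d / box);
  return d;
}

// deterministic PRNG: splitmix64-seeded xoshiro256++, Box-Muller normals
struct Rng {
  uint64_t s[4];
  double spare; bool has_spare = false;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double rr = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = rr * std::sin(th); has_spare = true;
    return rr * std::cos(th);
  }
};

typedef std::vector<double> Vec;

// nonbonded pair energy and force factor (force_i = fbyr * (xi - xj));
// accumulates into breakdown
static inline double pair_terms(double r2, int ci, int cj, int qi, int qj,
                                const Model& m, Breakdown& eb) {
  double fbyr = 0.0;
  if (r2 <= m.rc2_rep) {
    double s2 = (m.sigr * m.sigr) / r2;
    double sr12 = s2 * s2 * s2; sr12 *= sr12;
    double e = m.epsr * sr12;
    eb.rep += e;
    fbyr += 12.0 * e / r2;
  }
  bool aroaro = (ci == ARO && cj == ARO);
  bool catpi = m.incl_catpi &&
    ((ci == ARO && cj == POS) || (ci == POS && cj == ARO));
  if ((aroaro || catpi) && r2 < m.rc2_disp) {
    double eps = aroaro ? m.eps_pipi : m.eps_catpi;
    double shift = aroaro ? m.shift_pipi : m.shift_catpi;
    double s2 = (m.sigc * m.sigc) / r2;
    double sr6 = s2 * s2 * s2;
    eb.disp += eps * (sr6 * sr6 - 2.0 * sr6 - shift);
    fbyr += 12.0 * eps * (sr6 * sr6 - sr6) / r2;
  }
  int qq = qi * qj;
  if (qq != 0 && r2 < m.rc2_elec) {
    double r = std::sqrt(r2);
    double pref = m.kq * qq * m.Bfac / m.diel;
    double ex = std::exp(-m.kappaD * r);
    eb.elec += pref * (ex / r - m.elec_shift);
    fbyr += pref * ex * (m.kappaD * r + 1.0) / (r2 * r);
  }
  return fbyr;
}

static void bonded_forces(const Vec& x, const IntegerVector& chain,
                          double box, bool periodic, const Model& m,
                          Vec& f, Breakdown& eb) {
  int n = chain.size();
  for (int i = 0; i + 1 < n; i++) {
    if (chain[i + 1] != chain[i]) continue;
    double dx = min_image(x[3 * i] - x[3 * i + 3], box, periodic);
    double dy = min_image(x[3 * i + 1] - x[3 * i + 4], box, periodic);
    double dz = min_image(x[3 * i + 2] - x[3 * i + 5], box, periodic);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - m.r0;
    eb.bond += m.kb * dr * dr;
    double fbyr = -2.0 * m.kb * dr / r;
    f[3 * i] += fbyr * dx; f[3 * i + 1] += fbyr * dy; f[3 * i + 2] += fbyr * dz;
    f[3 * i + 3] -= fbyr * dx; f[3 * i + 4] -= fbyr * dy; f[3 * i + 5] -= fbyr * dz;
  }
  if (m.kth <= 0) return;
  for (int j = 1; j + 1 < n; j++) {
    if (chain[j - 1] != chain[j] || chain[j + 1] != chain[j]) continue;
    int i = j - 1, k = j + 1;
    double ax = min_image(x[3 * i] - x[3 * j], box, periodic);
    double ay = min_image(x[3 * i + 1] - x[3 * j + 1], box, periodic);
    double az = min_image(x[3 * i + 2] - x[3 * j + 2], box, periodic);
    double bx = min_image(x[3 * k] - x[3 * j], box, periodic);
    double by = min_image(x[3 * k + 1] - x[3 * j + 1], box, periodic);
    double bz = min_image(x[3 * k + 2] - x[3 * j + 2], box, periodic);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    double dot = ax * bx + ay * by + az * bz;
    double c = dot / (la * lb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - m.th0;
    eb.angle += m.kth * dth * dth;
    double sth = std::sqrt(1.0 - c * c);
    if (sth < 1e-8) sth = 1e-8;
    double coef = 2.0 * m.kth * dth / sth;  // dE/dtheta * dtheta/dcos = -coef
    // gradient of cos(theta) wrt endpoints
    double gax = bx / (la * lb) - c * ax / (la * la);
    double gay = by / (la * lb) - c * ay / (la * la);
    double gaz = bz / (la * lb) - c * az / (la * la);
    double gbx = ax / (la * lb) - c * bx / (lb * lb);
    double gby = ay / (la * lb) - c * by / (lb * lb);
    double gbz = az / (la * lb) - c * bz / (lb * lb);
    // F_i = -dE/dr_i = +coef * d(cos)/dr_i since dtheta/dcos = -1/sin
    f[3 * i] += coef * gax; f[3 * i + 1] += coef * gay; f[3 * i + 2] += coef * gaz;
    f[3 * k] += coef * gbx; f[3 * k + 1] += coef * gby; f[3 * k + 2] += coef * gbz;
    f[3 * j] -= coef * (gax + gbx);
    f[3 * j + 1] -= coef * (gay + gby);
    f[3 * j + 2] -= coef * (gaz + gbz);
  }
}

// neighbour list of nonbonded pairs (1-2 and 1-3 same-chain pairs excluded)
static void build_pairs(const Vec& x, const IntegerVector& chain,
                        double box, bool periodic, double rlist,
                        std::vector<std::pair<int, int> >& pairs) {
  pairs.clear();
  int n = chain.size();
  double rl2 = rlist * rlist;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      if (chain[i] == chain[j] && j - i <= 2) continue;
      double dx = min_image(x[3 * i] - x[3 * j], box, periodic);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, periodic);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, periodic);
      if (dx * dx + dy * dy + dz * dz < rl2) pairs.push_back({i, j});
    }
  }
}

static void nonbonded_forces(const Vec& x, const IntegerVector& cls,
                             const std::vector<int>& q,
                             const std::vector<std::pair<int, int> >& pairs,
                             double box, bool periodic, const Model& m,
                             Vec& f, Breakdown& eb) {
  for (size_t p = 0; p < pairs.size(); p++) {
    int i = pairs[p].first, j = pairs[p].second;
    double dx = min_image(x[3 * i] - x[3 * j], box, periodic);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box, periodic);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box, periodic);
    double r2 = dx * dx + dy * dy + dz * dz;
    double fbyr = pair_terms(r2, cls[i], cls[j], q[i], q[j], m, eb);
    if (fbyr != 0.0) {
      f[3 * i] += fbyr * dx; f[3 * i + 1] += fbyr * dy; f[3 * i + 2] += fbyr * dz;
      f[3 * j] -= fbyr * dx; f[3 * j + 1] -= fbyr * dy; f[3 * j + 2] -= fbyr * dz;
    }
  }
}

static std::vector<int> charges_of(const IntegerVector& cls) {
  std::vector<int> q(cls.size(), 0);
  for (int i = 0; i < cls.size(); i++) {
    if (cls[i] == POS) q[i] = 1;
    else if (cls[i] == NEG) q[i] = -1;
  }
  return q;
}

static double max_cutoff(const Model& m) {
  double rc = std::max(m.rc_rep, m.rc_disp);
  if (m.rc_elec < 1e7) rc = std::max(rc, m.rc_elec);
  else rc = 1e8;
  return rc;
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix positions, IntegerVector classes,
                       IntegerVector chain, double box, bool periodic,
                       List ff, bool all_pairs = true, double skin = 0.0) {
  Model m = parse_model(ff);
  int n = positions.nrow();
  Vec x(3 * n);
  for (int i = 0; i < n; i++) {
    x[3 * i] = positions(i, 0);
    x[3 * i + 1] = positions(i, 1);
    x[3 * i + 2] = positions(i, 2);
  }
  std::vector<int> q = charges_of(classes);
  std::vector<std::pair<int, int> > pairs;
  double rlist = all_pairs ? 1e9 : max_cutoff(m) + skin;
  if (periodic && rlist > box * 10) rlist = box * 10;
  build_pairs(x, chain, box, periodic, rlist, pairs);
  Vec f(3 * n, 0.0);
  Breakdown eb;
  nonbonded_forces(x, classes, q, pairs, box, periodic, m, f, eb);
  bonded_forces(x, chain, box, periodic, m, f, eb);
  NumericMatrix fr(n, 3);
  for (int i = 0; i < n; i++) {
    fr(i, 0) = f[3 * i]; fr(i, 1) = f[3 * i + 1]; fr(i, 2) = f[3 * i + 2];
  }
  return List::create(
    _["electrostatic"] = eb.elec, _["dispersion"] = eb.disp,
    _["repulsion"] = eb.rep, _["bond"] = eb.bond, _["angle"] = eb.angle,
    _["total"] = eb.total(), _["forces"] = fr);
}

// [[Rcpp::export]]
List langevin_cpp(NumericMatrix positions, IntegerVector classes,
                  IntegerVector chain, double box, bool periodic,
                  List ff, double dt, double gamma, double kT,
                  int n_steps, int save_every, double seed,
                  double skin = 2.0) {
  Model m = parse_model(ff);
  int n = positions.nrow();
  Vec x(3 * n), v(3 * n), f(3 * n, 0.0), x_ref(3 * n);
  for (int i = 0; i < n; i++) {
    x[3 * i] = positions(i, 0);
    x[3 * i + 1] = positions(i, 1);
    x[3 * i + 2] = positions(i, 2);
  }
  std::vector<int> q = charges_of(classes);
  Rng rng((uint64_t)(seed >= 0 ? seed : -seed) + 1ULL);

  // Maxwell-Boltzmann start
  double sv = std::sqrt(kT);
  for (int i = 0; i < 3 * n; i++) v[i] = sv * rng.normal();

  double rlist = max_cutoff(m) + skin;
  bool use_all = false;
  if (periodic && rlist >= box / 2.0) { rlist = 1e9; use_all = true; }
  if (!periodic && rlist > 1e7) { rlist = 1e9; use_all = true; }
  std::vector<std::pair<int, int> > pairs;
  build_pairs(x, chain, box, periodic, rlist, pairs);
  x_ref = x;

  Breakdown eb;
  nonbonded_forces(x, classes, q, pairs, box, periodic, m, f, eb);
  bonded_forces(x, chain, box, periodic, m, f, eb);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(kT * (1.0 - c1 * c1));
  int n_save = n_steps / save_every + 1;
  NumericVector frames((R_xlen_t)n_save * n * 3);
  IntegerVector steps(n_save);
  NumericMatrix etab(n_save, 8);  // elec disp rep bond angle total ekin T
  colnames(etab) = CharacterVector::create("electrostatic", "dispersion",
    "repulsion", "bond", "angle", "potential", "kinetic", "temperature");
  int isave = 0;
  bool ok = true;
  double kB = 0.0019872041;

  auto snapshot = [&](int step) {
    double ekin = 0.0;
    for (int i = 0; i < 3 * n; i++) ekin += 0.5 * v[i] * v[i];
    steps[isave] = step;
    etab(isave, 0) = eb.elec; etab(isave, 1) = eb.disp;
    etab(isave, 2) = eb.rep; etab(isave, 3) = eb.bond;
    etab(isave, 4) = eb.angle; etab(isave, 5) = eb.total();
    etab(isave, 6) = ekin;
    etab(isave, 7) = 2.0 * ekin / (3.0 * n * kB);
    for (int i = 0; i < 3 * n; i++)
      frames[(R_xlen_t)isave * 3 * n + i] = x[i];
    isave++;
  };
  snapshot(0);

  int done_steps = 0;
  for (int step = 1; step <= n_steps; step++) {
    for (int i = 0; i < 3 * n; i++) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * n; i++) x[i] += 0.5 * dt * v[i];
    if (gamma > 0 || kT > 0) {
      for (int i = 0; i < 3 * n; i++)
        v[i] = c1 * v[i] + c2 * rng.normal();
    }
    for (int i = 0; i < 3 * n; i++) x[i] += 0.5 * dt * v[i];

    if (!use_all) {
      double max_d2 = 0.0;
      for (int i = 0; i < n; i++) {
        double dx = x[3 * i] - x_ref[3 * i];
        double dy = x[3 * i + 1] - x_ref[3 * i + 1];
        double dz = x[3 * i + 2] - x_ref[3 * i + 2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > max_d2) max_d2 = d2;
      }
      if (max_d2 > 0.25 * skin * skin) {
        build_pairs(x, chain, box, periodic, rlist, pairs);
        x_ref = x;
      }
    }
    std::fill(f.begin(), f.end(), 0.0);
    eb.reset();
    nonbonded_forces(x, classes, q, pairs, box, periodic, m, f, eb);
    bonded_forces(x, chain, box, periodic, m, f, eb);
    for (int i = 0; i < 3 * n; i++) v[i] += 0.5 * dt * f[i];

    if (!std::isfinite(eb.total())) { ok = false; done_steps = step; break; }
    if (step % save_every == 0) snapshot(step);
    done_steps = step;
  }

  // trim unused snapshot slots on abort
  if (isave < n_save) {
    steps = IntegerVector(steps.begin(), steps.begin() + isave);
    NumericMatrix et2(isave, 8);
    for (int r = 0; r < isave; r++)
      for (int c = 0; c < 8; c++) et2(r, c) = etab(r, c);
    colnames(et2) = CharacterVector::create("electrostatic", "dispersion",
      "repulsion", "bond", "angle", "potential", "kinetic", "temperature");
    etab = et2;
    frames = NumericVector(frames.begin(), frames.begin() +
                           (R_xlen_t)isave * 3 * n);
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; i++) {
    xf(i, 0) = x[3 * i]; xf(i, 1) = x[3 * i + 1]; xf(i, 2) = x[3 * i + 2];
    vf(i, 0) = v[3 * i]; vf(i, 1) = v[3 * i + 1]; vf(i, 2) = v[3 * i + 2];
  }
  return List::create(_["frames"] = frames, _["steps"] = steps,
                      _["energies"] = etab, _["n_saved"] = isave,
                      _["final_positions"] = xf, _["final_velocities"] = vf,
                      _["completed"] = ok, _["steps_done"] = done_steps);
}

// chain pairs with any interbead contact within cutoff (minimum image)
// [[Rcpp::export]]
IntegerMatrix chain_contact_pairs_cpp(NumericMatrix positions,
                                      IntegerVector chain, double box,
                                      bool periodic, double cutoff) {
  int n = positions.nrow();
  double c2 = cutoff * cutoff;
  int n_chain = 0;
  for (int i = 0; i < n; i++) if (chain[i] > n_chain) n_chain = chain[i];
  std::vector<std::vector<bool> > hit(n_chain + 1,
                                      std::vector<bool>(n_chain + 1, false));
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      if (chain[i] == chain[j]) continue;
      int a = chain[i], b = chain[j];
      if (hit[a][b]) continue;
      double dx = min_image(positions(i, 0) - positions(j, 0), box, periodic);
      double dy = min_image(positions(i, 1) - positions(j, 1), box, periodic);
      double dz = min_image(positions(i, 2) - positions(j, 2), box, periodic);
      if (dx * dx + dy * dy + dz * dz <= c2) { hit[a][b] = true; hit[b][a] = true; }
    }
  }
  std::vector<int> ai, bi;
  for (int a = 1; a <= n_chain; a++)
    for (int b = a + 1; b <= n_chain; b++)
      if (hit[a][b]) { ai.push_back(a); bi.push_back(b); }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); k++) { out(k, 0) = ai[k]; out(k, 1) = bi[k]; }
  return out;
}

// per-chain interchain nonbonded energy (kcal/mol); pair energy added to
// both partner chains
// [[Rcpp::export]]
NumericVector interchain_energy_cpp(NumericMatrix positions,
                                    IntegerVector classes,
                                    IntegerVector chain, double box,
                                    bool periodic, List ff) {
  Model m = parse_model(ff);
  int n = positions.nrow();
  int n_chain = 0;
  for (int i = 0; i < n; i++) if (chain[i] > n_chain) n_chain = chain[i];
  std::vector<int> q = charges_of(classes);
  NumericVector out(n_chain);
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      if (chain[i] == chain[j]) continue;
      double dx = min_image(positions(i, 0) - positions(j, 0), box, periodic);
      double dy = min_image(positions(i, 1) - positions(j, 1), box, periodic);
      double dz = min_image(positions(i, 2) - positions(j, 2), box, periodic);
      double r2 = dx * dx + dy * dy + dz * dz;
      Breakdown eb;
      pair_terms(r2, classes[i], classes[j], q[i], q[j], m, eb);
      double e = eb.total();
      if (e != 0.0) {
        out[chain[i] - 1] += e;
        out[chain[j] - 1] += e;
      }
    }
  }
  return out;
}

// minimum interbead distance (diagnostics for initial configurations)
// [[Rcpp::export]]
double min_pair_distance_cpp(NumericMatrix positions, double box,
                             bool periodic) {
  int n = positions.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = min_image(positions(i, 0) - positions(j, 0), box, periodic);
      double dy = min_image(positions(i, 1) - positions(j, 1), box, periodic);
      double dz = min_image(positions(i, 2) - positions(j, 2), box, periodic);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
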