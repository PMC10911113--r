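// Compiled core: pair-term energies/forces and the BAOAB Langevin integrator.
// Units: A, fs, amu, kcal/mol, e, K.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double ACC_CONV = 4.184e-4;   // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872041;     // kcal/(mol K)

// ---------------------------------------------------------------------------
// Deterministic RNG: splitmix64-seeded xoshiro256**, uniforms via 53-bit
// mantissa, normals via Marsaglia polar (implementation-defined std::
// distributions are avoided so streams are reproducible everywhere).
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
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
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
struct PairList1210 { std::vector<int> i, j; std::vector<double> sig, del, cut2; };
struct System {
  int n = 0;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bK, br0;
  // angles (i - j - k, vertex j)
  std::vector<int> ai, aj, ak; std::vector<double> aK, acos0;
  PairList1210 stack, hb;
  // WCA
  std::vector<int> wi, wj; std::vector<double> wsig; double weps = 4.0;
  // Debye-Hueckel
  std::vector<int> di, dj; std::vector<double> dpref; double kappa = 10.0, dcut2 = 1225.0;
  // HPS (Ashbaugh-Hatch)
  std::vector<int> hi, hj; std::vector<double> hsig, hlam; double heps = 0.2;
  double hps_cut_factor = 3.0;
};

static void parse_pairs(const List& l, PairList1210& p) {
  IntegerVector i = l["i"], j = l["j"];
  NumericVector s = l["sigma"], d = l["delta"], c = l["cutoff"];
  int m = i.size();
  p.i.assign(i.begin(), i.end()); p.j.assign(j.begin(), j.end());
  p.sig.assign(s.begin(), s.end()); p.del.assign(d.begin(), d.end());
  p.cut2.resize(m);
  for (int k = 0; k < m; k++) p.cut2[k] = c[k] * c[k];
}

static System parse_system(const List& sys) {
  System S;
  S.n = as<int>(sys["n"]);
  List b = sys["bonds"];
  { IntegerVector i = b["i"], j = b["j"]; NumericVector K = b["K"], r0 = b["r0"];
    S.bi.assign(i.begin(), i.end()); S.bj.assign(j.begin(), j.end());
    S.bK.assign(K.begin(), K.end()); S.br0.assign(r0.begin(), r0.end()); }
  List a = sys["angles"];
  { IntegerVector i = a["i"], j = a["j"], k = a["k"]; NumericVector K = a["K"], c0 = a["cos0"];
    S.ai.assign(i.begin(), i.end()); S.aj.assign(j.begin(), j.end()); S.ak.assign(k.begin(), k.end());
    S.aK.assign(K.begin(), K.end()); S.acos0.assign(c0.begin(), c0.end()); }
  parse_pairs(sys["stacking"], S.stack);
  parse_pairs(sys["hb"], S.hb);
  List w = sys["wca"];
  { IntegerVector i = w["i"], j = w["j"]; NumericVector s = w["sigma"];
    S.wi.assign(i.begin(), i.end()); S.wj.assign(j.begin(), j.end());
    S.wsig.assign(s.begin(), s.end()); S.weps = as<double>(w["eps"]); }
  List d = sys["dh"];
  { IntegerVector i = d["i"], j = d["j"]; NumericVector p = d["prefactor"];
    S.di.assign(i.begin(), i.end()); S.dj.assign(j.begin(), j.end());
    S.dpref.assign(p.begin(), p.end());
    S.kappa = as<double>(d["kappa"]);
    double cut = as<double>(d["cutoff"]); S.dcut2 = cut * cut; }
  List h = sys["hps"];
  { IntegerVector i = h["i"], j = h["j"]; NumericVector s = h["sigma"], l = h["lambda"];
    S.hi.assign(i.begin(), i.end()); S.hj.assign(j.begin(), j.end());
    S.hsig.assign(s.begin(), s.end()); S.hlam.assign(l.begin(), l.end());
    S.heps = as<double>(h["eps"]);
    S.hps_cut_factor = as<double>(h["cut_factor"]); }
  return S;
}

struct Terms {
  double bond = 0, angle = 0, stack = 0, hb = 0, excl = 0, elec = 0, hps = 0, bias = 0;
  double total() const { return bond + angle + stack + hb + excl + elec + hps; }
};

struct Umbrella {
  bool active = false;
  std::vector<int> ga, gb;
  std::vector<double> wa, wb;  // mass fractions within each group
  double k = 0, d0 = 0;
};

static inline void mimage(double* d, const double* box, bool pbc) {
  if (!pbc) return;
  for (int c = 0; c < 3; c++) d[c] -= box[c] * std::nearbyint(d[c] / box[c]);
}

// energy + forces; forces accumulated into f (length 3n), energies into T
static void eval_forces(const std::vector<double>& x, const System& S,
                        const double* box, bool pbc, std::vector<double>& f,
                        Terms& T, const Umbrella& U, double* cv_out) {
  std::fill(f.begin(), f.end(), 0.0);
  T = Terms();
  double d[3];

  // bonds: K (r - r0)^2
  for (size_t m = 0; m < S.bi.size(); m++) {
    int i = S.bi[m], j = S.bj[m];
    for (int c = 0; c < 3; c++) d[c] = x[3 * i + c] - x[3 * j + c];
    mimage(d, box, pbc);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double r = std::sqrt(r2);
    if (r <= 1e-8) stop("overlapping bonded beads %d and %d", i + 1, j + 1);
    double dr = r - S.br0[m];
    T.bond += S.bK[m] * dr * dr;
    double fr = -2.0 * S.bK[m] * dr / r;  // dU/dr * (-1/r) for vector scaling
    for (int c = 0; c < 3; c++) { f[3 * i + c] += fr * d[c]; f[3 * j + c] -= fr * d[c]; }
  }

  // angles: K (cos th - cos th0)^2, vertex j
  for (size_t m = 0; m < S.ai.size(); m++) {
    int i = S.ai[m], j = S.aj[m], k = S.ak[m];
    double a[3], b[3];
    for (int c = 0; c < 3; c++) { a[c] = x[3 * i + c] - x[3 * j + c]; b[c] = x[3 * k + c] - x[3 * j + c]; }
    mimage(a, box, pbc); mimage(b, box, pbc);
    double la2 = a[0]*a[0]+a[1]*a[1]+a[2]*a[2], lb2 = b[0]*b[0]+b[1]*b[1]+b[2]*b[2];
    double la = std::sqrt(la2), lb = std::sqrt(lb2);
    double ct = (a[0]*b[0]+a[1]*b[1]+a[2]*b[2]) / (la * lb);
    if (ct > 1) ct = 1; if (ct < -1) ct = -1;
    double dc = ct - S.acos0[m];
    T.angle += S.aK[m] * dc * dc;
    double pref = -2.0 * S.aK[m] * dc;  // = -dU/dcos
    for (int c = 0; c < 3; c++) {
      double gi = (b[c] / (la * lb)) - ct * a[c] / la2;  // dcos/da_c
      double gk = (a[c] / (la * lb)) - ct * b[c] / lb2;
      f[3 * i + c] += pref * gi;
      f[3 * k + c] += pref * gk;
      f[3 * j + c] -= pref * (gi + gk);
    }
  }

  // 12-10 pairs (stacking + HB): delta (5 s^12 - 6 s^10), truncated
  for (int which = 0; which < 2; which++) {
    const PairList1210& P = which ? S.hb : S.stack;
    double& E = which ? T.hb : T.stack;
    for (size_t m = 0; m < P.i.size(); m++) {
      int i = P.i[m], j = P.j[m];
      for (int c = 0; c < 3; c++) d[c] = x[3 * i + c] - x[3 * j + c];
      mimage(d, box, pbc);
      double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (r2 >= P.cut2[m]) continue;
      if (r2 <= 1e-16) stop("overlapping beads %d and %d", i + 1, j + 1);
      double s2 = P.sig[m] * P.sig[m] / r2;
      double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
      E += P.del[m] * (5.0 * s12 - 6.0 * s10);
      double fr = P.del[m] * 60.0 * (s12 - s10) / r2;  // -dU/dr / r
      for (int c = 0; c < 3; c++) { f[3*i+c] += fr * d[c]; f[3*j+c] -= fr * d[c]; }
    }
  }

  // WCA
  for (size_t m = 0; m < S.wi.size(); m++) {
    int i = S.wi[m], j = S.wj[m];
    for (int c = 0; c < 3; c++) d[c] = x[3 * i + c] - x[3 * j + c];
    mimage(d, box, pbc);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    double sig2 = S.wsig[m] * S.wsig[m];
    if (r2 >= sig2 * 1.2599210498948732) continue;  // (2^{1/6} sigma)^2
    if (r2 <= 1e-16) stop("overlapping beads %d and %d", i + 1, j + 1);
    double s2 = sig2 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    T.excl += 4.0 * S.weps * (s12 - s6) + S.weps;
    double fr = 4.0 * S.weps * (12.0 * s12 - 6.0 * s6) / r2;
    for (int c = 0; c < 3; c++) { f[3*i+c] += fr * d[c]; f[3*j+c] -= fr * d[c]; }
  }

  // Debye-Hueckel
  for (size_t m = 0; m < S.di.size(); m++) {
    int i = S.di[m], j = S.dj[m];
    for (int c = 0; c < 3; c++) d[c] = x[3 * i + c] - x[3 * j + c];
    mimage(d, box, pbc);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= S.dcut2) continue;
    double r = std::sqrt(r2);
    if (r <= 1e-8) stop("overlapping charged beads %d and %d", i + 1, j + 1);
    double u = S.dpref[m] * std::exp(-r / S.kappa) / r;
    T.elec += u;
    double fr = u * (1.0 / (r * S.kappa) + 1.0 / r2);  // -dU/dr / r
    for (int c = 0; c < 3; c++) { f[3*i+c] += fr * d[c]; f[3*j+c] -= fr * d[c]; }
  }

  // HPS (Ashbaugh-Hatch split at 2^{1/6} sigma, truncated at cut_factor*sigma)
  for (size_t m = 0; m < S.hi.size(); m++) {
    int i = S.hi[m], j = S.hj[m];
    for (int c = 0; c < 3; c++) d[c] = x[3 * i + c] - x[3 * j + c];
    mimage(d, box, pbc);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    double sig = S.hsig[m], lam = S.hlam[m];
    double cut = S.hps_cut_factor * sig;
    if (r2 >= cut * cut) continue;
    if (r2 <= 1e-16) stop("overlapping beads %d and %d", i + 1, j + 1);
    double s2 = sig * sig / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    double ulj = 4.0 * S.heps * (s12 - s6);
    double flj = 4.0 * S.heps * (12.0 * s12 - 6.0 * s6) / r2;  // -dU/dr / r
    if (r2 <= sig * sig * 1.2599210498948732) {
      T.hps += ulj + (1.0 - lam) * S.heps;
      for (int c = 0; c < 3; c++) { f[3*i+c] += flj * d[c]; f[3*j+c] -= flj * d[c]; }
    } else {
      T.hps += lam * ulj;
      for (int c = 0; c < 3; c++) { f[3*i+c] += lam * flj * d[c]; f[3*j+c] -= lam * flj * d[c]; }
    }
  }

  // umbrella bias on mass-weighted COM-COM distance: k (d - d0)^2
  if (U.active) {
    double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
    for (size_t m = 0; m < U.ga.size(); m++)
      for (int c = 0; c < 3; c++) ca[c] += U.wa[m] * x[3 * U.ga[m] + c];
    for (size_t m = 0; m < U.gb.size(); m++)
      for (int c = 0; c < 3; c++) cb[c] += U.wb[m] * x[3 * U.gb[m] + c];
    double dd[3] = {ca[0] - cb[0], ca[1] - cb[1], ca[2] - cb[2]};
    // COMs are not minimum-imaged: umbrella systems keep both groups well
    // inside one periodic image
    double dist = std::sqrt(dd[0]*dd[0] + dd[1]*dd[1] + dd[2]*dd[2]);
    if (cv_out) *cv_out = dist;
    double dr = dist - U.d0;
    T.bias = U.k * dr * dr;
    if (dist > 1e-10) {
      double pref = -2.0 * U.k * dr / dist;
      for (size_t m = 0; m < U.ga.size(); m++)
        for (int c = 0; c < 3; c++) f[3 * U.ga[m] + c] += pref * U.wa[m] * dd[c];
      for (size_t m = 0; m < U.gb.size(); m++)
        for (int c = 0; c < 3; c++) f[3 * U.gb[m] + c] -= pref * U.wb[m] * dd[c];
    }
  }
}

static Umbrella parse_umbrella(SEXP usxp, const NumericVector& mass) {
  Umbrella U;
  if (Rf_isNull(usxp)) return U;
  List ul(usxp);
  U.active = true;
  IntegerVector ga = ul["groupA"], gb = ul["groupB"];
  U.ga.assign(ga.begin(), ga.end()); U.gb.assign(gb.begin(), gb.end());
  U.k = as<double>(ul["k"]); U.d0 = as<double>(ul["d0"]);
  double ma = 0, mb = 0;
  for (int g : U.ga) ma += mass[g];
  for (int g : U.gb) mb += mass[g];
  U.wa.resize(U.ga.size()); U.wb.resize(U.gb.size());
  for (size_t m = 0; m < U.ga.size(); m++) U.wa[m] = mass[U.ga[m]] / ma;
  for (size_t m = 0; m < U.gb.size(); m++) U.wb[m] = mass[U.gb[m]] / mb;
  return U;
}

// [[Rcpp::export(name = ".cg_energy_forces")]]
List cg_energy_forces(NumericMatrix positions, List sys, NumericVector box,
                      bool pbc, SEXP umbrella = R_NilValue,
                      Nullable<NumericVector> masses = R_NilValue) {
  System S = parse_system(sys);
  int n = positions.nrow();
  if (n != S.n) stop("coordinate/topology size mismatch");
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; i++)
    for (int c = 0; c < 3; c++) x[3 * i + c] = positions(i, c);
  NumericVector mv = masses.isNotNull() ? NumericVector(masses) : NumericVector(n, 1.0);
  Umbrella U = parse_umbrella(umbrella, mv);
  Terms T; double cv = NA_REAL;
  eval_forces(x, S, &box[0], pbc, f, T, U, &cv);
  NumericMatrix fo(n, 3);
  for (int i = 0; i < n; i++)
    for (int c = 0; c < 3; c++) fo(i, c) = f[3 * i + c];
  return List::create(
    _["terms"] = NumericVector::create(
      _["bond"] = T.bond, _["angle"] = T.angle, _["stacking"] = T.stack,
      _["hb"] = T.hb, _["excluded"] = T.excl, _["electrostatics"] = T.elec,
      _["hps"] = T.hps),
    _["total"] = T.total(), _["bias"] = T.bias, _["cv"] = cv, _["forces"] = fo);
}

// [[Rcpp::export(name = ".cg_run_langevin")]]
List cg_run_langevin(NumericMatrix positions, SEXP velocities, NumericVector mass,
                     List sys, List settings) {
  System S = parse_system(sys);
  int n = positions.nrow();
  if (n != S.n) stop("coordinate/topology size mismatch");

  double dt = as<double>(settings["dt"]);                // fs
  double temperature = as<double>(settings["temperature"]);
  double tau_ps = as<double>(settings["tau"]);           // ps; <= 0 -> no thermostat
  long n_steps = (long)as<double>(settings["n_steps"]);
  int stride = as<int>(settings["stride"]);
  double seed = as<double>(settings["seed"]);
  bool pbc = as<bool>(settings["pbc"]);
  NumericVector box = settings["box"];
  int cv_stride = as<int>(settings["cv_stride"]);
  Umbrella U = parse_umbrella(settings.containsElementNamed("umbrella") ?
                              (SEXP)settings["umbrella"] : R_NilValue, mass);

  Rng rng((uint64_t)seed);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; i++)
    for (int c = 0; c < 3; c++) x[3 * i + c] = positions(i, c);
  if (Rf_isNull(velocities)) {
    for (int i = 0; i < n; i++) {
      double sd = std::sqrt(KB * temperature / mass[i] * ACC_CONV);  // A/fs
      for (int c = 0; c < 3; c++) v[3 * i + c] = sd * rng.normal();
    }
  } else {
    NumericMatrix vm(velocities);
    for (int i = 0; i < n; i++)
      for (int c = 0; c < 3; c++) v[3 * i + c] = vm(i, c);
  }

  bool thermostat = tau_ps > 0;
  double afac = thermostat ? std::exp(-dt / (1000.0 * tau_ps)) : 1.0;
  std::vector<double> bfac(n);
  for (int i = 0; i < n; i++)
    bfac[i] = thermostat ?
      std::sqrt((1.0 - afac * afac) * KB * temperature / mass[i] * ACC_CONV) : 0.0;

  int n_frames = (stride > 0) ? (int)(n_steps / stride) : 0;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  std::vector<double> e_bond, e_angle, e_stack, e_hb, e_excl, e_elec, e_hps,
      e_pot, e_kin, e_bias, tkin;
  long n_cv = (cv_stride > 0 && U.active) ? n_steps / cv_stride : 0;
  NumericVector cvs(n_cv);

  Terms T;
  double cv = NA_REAL;
  eval_forces(x, S, &box[0], pbc, f, T, U, &cv);

  int fidx = 0; long cidx = 0;
  for (long step = 1; step <= n_steps; step++) {
    // B: half kick
    for (int i = 0; i < n; i++) {
      double s = 0.5 * dt * ACC_CONV / mass[i];
      for (int c = 0; c < 3; c++) v[3 * i + c] += s * f[3 * i + c];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; i++) x[i] += 0.5 * dt * v[i];
    // O
    if (thermostat) {
      for (int i = 0; i < n; i++)
        for (int c = 0; c < 3; c++)
          v[3 * i + c] = afac * v[3 * i + c] + bfac[i] * rng.normal();
    }
    // A: half drift
    for (int i = 0; i < 3 * n; i++) x[i] += 0.5 * dt * v[i];
    // force refresh + B half kick
    eval_forces(x, S, &box[0], pbc, f, T, U, &cv);
    for (int i = 0; i < n; i++) {
      double s = 0.5 * dt * ACC_CONV / mass[i];
      for (int c = 0; c < 3; c++) v[3 * i + c] += s * f[3 * i + c];
    }

    // stability check
    for (int i = 0; i < 3 * n; i++) {
      if (!std::isfinite(x[i]) || std::fabs(v[i]) * dt > 25.0)
        stop("numeric blow-up at step %ld (bead %d)", step, i / 3 + 1);
    }

    if (U.active && cv_stride > 0 && step % cv_stride == 0 && cidx < n_cv)
      cvs[cidx++] = cv;

    if (stride > 0 && step % stride == 0 && fidx < n_frames) {
      double ke = 0;
      for (int i = 0; i < n; i++) {
        double v2 = 0;
        for (int c = 0; c < 3; c++) v2 += v[3 * i + c] * v[3 * i + c];
        ke += 0.5 * mass[i] * v2;
      }
      ke /= ACC_CONV;  // kcal/mol
      e_bond.push_back(T.bond); e_angle.push_back(T.angle);
      e_stack.push_back(T.stack); e_hb.push_back(T.hb);
      e_excl.push_back(T.excl); e_elec.push_back(T.elec); e_hps.push_back(T.hps);
      e_pot.push_back(T.total()); e_kin.push_back(ke); e_bias.push_back(T.bias);
      tkin.push_back(2.0 * ke / (3.0 * n * KB));
      for (int i = 0; i < n; i++)
        for (int c = 0; c < 3; c++)
          frames[(R_xlen_t)fidx * 3 * n + 3 * i + c] = x[3 * i + c];
      fidx++;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; i++)
    for (int c = 0; c < 3; c++) { xo(i, c) = x[3 * i + c]; vo(i, c) = v[3 * i + c]; }

  return List::create(
    _["frames"] = frames, _["n_frames"] = fidx,
    _["energies"] = DataFrame::create(
      _["bond"] = e_bond, _["angle"] = e_angle, _["stacking"] = e_stack,
      _["hb"] = e_hb, _["excluded"] = e_excl, _["electrostatics"] = e_elec,
      _["hps"] = e_hps, _["potential"] = e_pot, _["kinetic"] = e_kin,
      _["bias"] = e_bias, _["kinetic_temperature"] = tkin),
    _["cv"] = cvs,
    _["positions"] = xo, _["velocities"] = vo);
}
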