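// Monte Carlo transport kernel: CSG source geometry, analog photon
// transport, simplified condensed-history electron transport, and
// spherical (r, theta) tally scoring.
//
// All lengths cm, energies keV, angles internally radians (tally spec in
// degrees).  The z axis is the source axis, tip side positive, theta
// measured from +z.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64; one independent stream per
// history, keyed by (master seed, global history index).

struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (stream * 0xD2B74407B1CE6E93ULL + 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double u() { return (next() >> 11) * 1.1102230246251565e-16; } // (0,1)
  double uo() { double v; do { v = u(); } while (v <= 0.0); return v; }
  double normal() {  // polar Box-Muller, single value (discard pair partner)
    double a, b, r2;
    do { a = 2.0 * u() - 1.0; b = 2.0 * u() - 1.0; r2 = a * a + b * b; }
    while (r2 >= 1.0 || r2 == 0.0);
    return a * std::sqrt(-2.0 * std::log(r2) / r2);
  }
};

// ----------------------------------------------------------- geometry -----

enum Region { R_CORE = 0, R_GAP = 1, R_CAPSULE = 2, R_CABLE = 3,
              R_PHANTOM = 4, R_OUTSIDE = 5 };

static const double EPS_NUDGE = 1e-9;

struct Geom {
  // source assembly
  double rcore, hcore, redge;          // active core cylinder + edge fillet
  double rcav, zcav_lo, zcav_hi;       // capsule cavity (== core for v2)
  double rcap, zback, ztipc, rtip;     // capsule outer cylinder + tip sphere
  double rcable, zcab_lo;              // drive cable
  bool has_gap, rounded;
  double rsrc2;                        // bounding sphere^2 of the assembly
  // phantom: either a water sphere or concentric air shells in vacuum
  double rph;                          // outer phantom radius
  bool shells;                         // air-shell phantom?
  std::vector<double> zone_r;          // radial zone boundaries (sorted, ends at rph)
  std::vector<int> zone_mat;           // material id per radial zone
  int mat[6];                          // region -> material id (phantom entry is
                                       // the uniform-medium case)

  bool in_core(double x, double y, double z) const {
    double r2 = x * x + y * y, az = std::fabs(z);
    if (!rounded) return r2 <= rcore * rcore && az <= hcore;
    return (r2 <= rcore * rcore && az <= hcore - redge) ||
           (r2 <= (rcore - redge) * (rcore - redge) && az <= hcore);
  }
  bool in_cavity(double x, double y, double z) const {
    if (!has_gap) return in_core(x, y, z);
    return x * x + y * y <= rcav * rcav && z >= zcav_lo && z <= zcav_hi;
  }
  bool in_capsule_outer(double x, double y, double z) const {
    double r2 = x * x + y * y;
    if (r2 <= rcap * rcap && z >= zback && z <= ztipc) return true;
    double dz = z - ztipc;
    return z > ztipc && r2 + dz * dz <= rtip * rtip;
  }
  bool in_cable(double x, double y, double z) const {
    return x * x + y * y <= rcable * rcable && z >= zcab_lo && z < zback;
  }
  int zone_of(double r) const {  // radial zone index for shell phantoms
    int lo = 0, hi = (int)zone_r.size();  // zone i: (zone_r[i-1], zone_r[i]]
    while (lo < hi) { int m = (lo + hi) / 2; if (r <= zone_r[m]) hi = m; else lo = m + 1; }
    return lo;
  }
  int locate(double x, double y, double z) const {
    double d2 = x * x + y * y + z * z;
    if (d2 <= rsrc2) {
      if (in_core(x, y, z)) return R_CORE;
      if (has_gap && in_cavity(x, y, z)) return R_GAP;
      if (in_capsule_outer(x, y, z)) return R_CAPSULE;
      if (in_cable(x, y, z)) return R_CABLE;
    }
    if (d2 < rph * rph) return R_PHANTOM;
    return R_OUTSIDE;
  }
  int material_at(double x, double y, double z, int region) const {
    if (region != R_PHANTOM || !shells) return mat[region];
    int zi = zone_of(std::sqrt(x * x + y * y + z * z));
    if (zi >= (int)zone_mat.size()) zi = (int)zone_mat.size() - 1;
    return zone_mat[zi];
  }
};

static const double INF_D = 1e30;

// smallest positive root helpers; every surface is treated as a candidate
// plane/quadric with a finite cap; stepping across a surface that does not
// actually separate two regions is harmless (the flight is resampled).
static inline void hit_plane_z(double pz, double uz, double zc,
                               double px, double py, double ux, double uy,
                               double rmax, double &best) {
  if (uz == 0.0) return;
  double t = (zc - pz) / uz;
  if (t <= EPS_NUDGE || t >= best) return;
  double x = px + t * ux, y = py + t * uy;
  if (x * x + y * y <= rmax * rmax) best = t;
}
static inline void hit_cyl(double px, double py, double pz,
                           double ux, double uy, double uz,
                           double R, double zlo, double zhi, double &best) {
  double a = ux * ux + uy * uy;
  if (a <= 0.0) return;
  double b = px * ux + py * uy;
  double c = px * px + py * py - R * R;
  double disc = b * b - a * c;
  if (disc < 0.0) return;
  double sd = std::sqrt(disc);
  for (int i = 0; i < 2; ++i) {
    double t = (i == 0) ? (-b - sd) / a : (-b + sd) / a;
    if (t <= EPS_NUDGE || t >= best) continue;
    double z = pz + t * uz;
    if (z >= zlo && z <= zhi) { best = t; return; }
  }
}
static inline void hit_sphere(double px, double py, double pz,
                              double ux, double uy, double uz,
                              double cz, double R, double &best) {
  double dz = pz - cz;
  double b = px * ux + py * uy + dz * uz;
  double c = px * px + py * py + dz * dz - R * R;
  double disc = b * b - c;
  if (disc < 0.0) return;
  double sd = std::sqrt(disc);
  double t = -b - sd;
  if (t > EPS_NUDGE && t < best) { best = t; return; }
  t = -b + sd;
  if (t > EPS_NUDGE && t < best) best = t;
}

// distance to the next region boundary along u (may stop at an internal
// construction surface; the caller re-locates after the step)
static double boundary_distance(const Geom &g, double px, double py, double pz,
                                double ux, double uy, double uz, int region) {
  double best = INF_D;
  double d2 = px * px + py * py + pz * pz;
  // closest approach to the source assembly
  bool near_src = true;
  if (region == R_PHANTOM && d2 > g.rsrc2) {
    double tc = -(px * ux + py * uy + pz * uz);
    if (tc < 0.0) near_src = false;
    else {
      double m2 = d2 - tc * tc;
      near_src = (m2 <= g.rsrc2);
    }
  }
  if (near_src) {
    double h1 = g.hcore - g.redge, r2c = g.rcore - g.redge;
    if (g.rounded) {
      hit_cyl(px, py, pz, ux, uy, uz, g.rcore, -h1, h1, best);
      hit_plane_z(pz, uz, h1, px, py, ux, uy, g.rcore, best);
      hit_plane_z(pz, uz, -h1, px, py, ux, uy, g.rcore, best);
      hit_cyl(px, py, pz, ux, uy, uz, r2c, -g.hcore, g.hcore, best);
      hit_plane_z(pz, uz, g.hcore, px, py, ux, uy, r2c, best);
      hit_plane_z(pz, uz, -g.hcore, px, py, ux, uy, r2c, best);
    } else {
      hit_cyl(px, py, pz, ux, uy, uz, g.rcore, -g.hcore, g.hcore, best);
      hit_plane_z(pz, uz, g.hcore, px, py, ux, uy, g.rcore, best);
      hit_plane_z(pz, uz, -g.hcore, px, py, ux, uy, g.rcore, best);
    }
    if (g.has_gap) {
      hit_cyl(px, py, pz, ux, uy, uz, g.rcav, g.zcav_lo, g.zcav_hi, best);
      hit_plane_z(pz, uz, g.zcav_lo, px, py, ux, uy, g.rcav, best);
      hit_plane_z(pz, uz, g.zcav_hi, px, py, ux, uy, g.rcav, best);
    }
    hit_cyl(px, py, pz, ux, uy, uz, g.rcap, g.zback, g.ztipc, best);
    hit_sphere(px, py, pz, ux, uy, uz, g.ztipc, g.rtip, best);
    hit_plane_z(pz, uz, g.zback, px, py, ux, uy, g.rcap, best);
    hit_cyl(px, py, pz, ux, uy, uz, g.rcable, g.zcab_lo, g.zback, best);
    hit_plane_z(pz, uz, g.zcab_lo, px, py, ux, uy, g.rcable, best);
  }
  // phantom boundaries
  if (region == R_PHANTOM && g.shells) {
    double r = std::sqrt(d2);
    int zi = g.zone_of(r);
    double r_out = (zi < (int)g.zone_r.size()) ? g.zone_r[zi] : g.rph;
    double r_in = (zi > 0) ? g.zone_r[zi - 1] : -1.0;
    hit_sphere(px, py, pz, ux, uy, uz, 0.0, r_out, best);
    if (r_in > 0.0) hit_sphere(px, py, pz, ux, uy, uz, 0.0, r_in, best);
  } else {
    hit_sphere(px, py, pz, ux, uy, uz, 0.0, g.rph, best);
  }
  return best;
}

// conservative (under-estimating) distance from p to the boundary of its
// region, used to skip ray-boundary checks in electron stepping
static double safety_distance(const Geom &g, double x, double y, double z,
                              int region) {
  double rho = std::sqrt(x * x + y * y), az = std::fabs(z);
  double r = std::sqrt(rho * rho + z * z);
  // distance to the outside of a bounding cylinder (underestimates the
  // distance to anything inside it)
  auto cyl_out = [](double rho, double az, double R, double h) {
    double dr = rho - R, dz = az - h;
    if (dr < 0) dr = 0; if (dz < 0) dz = 0;
    return std::sqrt(dr * dr + dz * dz);
  };
  double s = 0.0;
  switch (region) {
  case R_CORE: {
    double h1 = g.hcore - g.redge, r2 = g.rcore - g.redge;
    double d1 = (rho <= g.rcore && az <= h1)
                ? std::min(g.rcore - rho, h1 - az) : 0.0;
    double d2 = (rho <= r2 && az <= g.hcore)
                ? std::min(r2 - rho, g.hcore - az) : 0.0;
    s = std::max(d1, d2);
    break; }
  case R_GAP: {
    double din = std::min(g.rcav - rho,
                          std::min(g.zcav_hi - z, z - g.zcav_lo));
    double dcore = cyl_out(rho, az, g.rcore, g.hcore);
    s = std::min(din, dcore);
    break; }
  case R_CAPSULE: {
    double dz = z - g.ztipc;
    double dcyl = (rho <= g.rcap && z >= g.zback && z <= g.ztipc)
                  ? std::min(g.rcap - rho, std::min(z - g.zback, g.ztipc - z))
                  : 0.0;
    double dt = std::sqrt(rho * rho + dz * dz);
    double dsph = (dt <= g.rtip) ? g.rtip - dt : 0.0;
    double douter = std::max(dcyl, dsph);
    double dcav;
    if (g.has_gap) {
      double drc = rho - g.rcav, dzc = std::max(z - g.zcav_hi, g.zcav_lo - z);
      if (drc < 0) drc = 0; if (dzc < 0) dzc = 0;
      dcav = std::sqrt(drc * drc + dzc * dzc);
    } else {
      dcav = cyl_out(rho, az, g.rcore, g.hcore);
    }
    s = std::min(douter, dcav);
    break; }
  case R_CABLE:
    s = std::min(g.rcable - rho, std::min(g.zback - z, z - g.zcab_lo));
    break;
  case R_PHANTOM: {
    double rs = std::sqrt(g.rsrc2);
    if (g.shells) {
      int zi = g.zone_of(r);
      double r_out = (zi < (int)g.zone_r.size()) ? g.zone_r[zi] : g.rph;
      double r_in = (zi > 0) ? g.zone_r[zi - 1] : rs;
      s = std::min(r_out - r, r - std::max(r_in, rs));
    } else {
      s = std::min(g.rph - r, r - rs);
    }
    break; }
  default:
    s = 0.0;
  }
  return s > 0.0 ? s : 0.0;
}

static Geom parse_geom(const List &gl) {
  Geom g;
  g.rcore = gl["rcore"]; g.hcore = gl["hcore"]; g.redge = gl["redge"];
  g.rcav = gl["rcav"]; g.zcav_lo = gl["zcav_lo"]; g.zcav_hi = gl["zcav_hi"];
  g.rcap = gl["rcap"]; g.zback = gl["zback"];
  g.ztipc = gl["ztipc"]; g.rtip = gl["rtip"];
  g.rcable = gl["rcable"]; g.zcab_lo = gl["zcab_lo"];
  g.has_gap = as<bool>(gl["has_gap"]); g.rounded = as<bool>(gl["rounded"]);
  g.rph = gl["rph"];
  g.shells = as<bool>(gl["shells"]);
  if (g.shells) {
    g.zone_r = as<std::vector<double> >(gl["zone_r"]);
    g.zone_mat = as<std::vector<int> >(gl["zone_mat"]);
  }
  IntegerVector m = gl["mat"];
  for (int i = 0; i < 6; ++i) g.mat[i] = m[i];
  double ztip = g.ztipc + g.rtip, zlo = g.zcab_lo;
  double rr = std::max(std::fabs(ztip), std::fabs(zlo));
  rr = std::max(rr, g.rcap) * 1.0000001;
  g.rsrc2 = rr * rr;
  return g;
}

// ------------------------------------------------------ physics tables ----
// per-material tables resampled by R onto a uniform log-energy grid

struct Phys {
  double logE0, inv_dlog;
  int n, nmat;
  NumericMatrix pe, incoh, coh, tot, mutr, scol, csda;  // n x nmat
  NumericVector rho;
  // Rayleigh sampling: cumulative integral of F^2 over x = s^2, shared x grid
  NumericVector ray_x;            // s^2 grid
  NumericMatrix ray_cdf;          // nx x nmat, unnormalized cumulative
  // iridium-style K fluorescence
  NumericVector fl_edge, fl_pemit;        // per material (0 = none)
  NumericMatrix fl_e, fl_cp;              // 3 x nmat: line energies, cum probs
  NumericVector x0;                       // radiation length g/cm2 per material

  double look(const NumericMatrix &tab, double E, int m) const {
    double t = (std::log(E) - logE0) * inv_dlog;
    if (t <= 0.0) return tab(0, m);
    int i = (int)t;
    if (i >= n - 1) return tab(n - 1, m);
    double f = t - i;
    return tab(i, m) * (1.0 - f) + tab(i + 1, m) * f;
  }
};

static Phys parse_phys(const List &pl) {
  Phys p;
  p.logE0 = pl["logE0"]; p.inv_dlog = pl["inv_dlog"];
  p.pe = as<NumericMatrix>(pl["pe"]); p.incoh = as<NumericMatrix>(pl["incoh"]);
  p.coh = as<NumericMatrix>(pl["coh"]); p.tot = as<NumericMatrix>(pl["tot"]);
  p.mutr = as<NumericMatrix>(pl["mutr"]);
  p.scol = as<NumericMatrix>(pl["scol"]); p.csda = as<NumericMatrix>(pl["csda"]);
  p.rho = pl["rho"];
  p.n = p.pe.nrow(); p.nmat = p.pe.ncol();
  p.ray_x = pl["ray_x"]; p.ray_cdf = as<NumericMatrix>(pl["ray_cdf"]);
  p.fl_edge = pl["fl_edge"]; p.fl_pemit = pl["fl_pemit"];
  p.fl_e = as<NumericMatrix>(pl["fl_e"]); p.fl_cp = as<NumericMatrix>(pl["fl_cp"]);
  p.x0 = pl["x0"];
  return p;
}

// -------------------------------------------------------------- spectrum --
struct Spect {
  std::vector<double> cdf, elo, ehi;
  double sample(Rng &rng) const {
    double u = rng.u();
    size_t lo = 0, hi = cdf.size() - 1;
    while (lo < hi) { size_t m = (lo + hi) / 2; if (u <= cdf[m]) hi = m; else lo = m + 1; }
    if (elo[lo] == ehi[lo]) return elo[lo];
    return elo[lo] + rng.u() * (ehi[lo] - elo[lo]);
  }
};
static Spect parse_spect(const List &sl) {
  Spect s;
  s.cdf = as<std::vector<double> >(sl["cdf"]);
  s.elo = as<std::vector<double> >(sl["elo"]);
  s.ehi = as<std::vector<double> >(sl["ehi"]);
  return s;
}

// ----------------------------------------------------------------- tally --
struct Tally {
  bool window;                 // sparse windows vs contiguous edges
  std::vector<double> r_edges, th_edges;          // contiguous mode (deg)
  std::vector<double> r_c, r_h, th_c, th_h;       // window mode (deg)
  int nr, nth, nbin, nbatch;
  double rmax;                                    // radial extent of the grid
  std::vector<double> cur;                        // current-batch accumulator
  std::vector<double> bsum;                       // nbin x nbatch batch sums
  double gap_e, outside_e;                        // unscored deposits
  int score_mode;                                 // 0 dose, 1 kerma, 2 kerma-TL
  int medium;                                     // material id scored (kerma)

  static int find_edge(const std::vector<double> &e, double v) {
    if (v < e.front() || v >= e.back()) return -1;
    int lo = 0, hi = (int)e.size() - 1;
    while (hi - lo > 1) { int m = (lo + hi) / 2; if (v < e[m]) hi = m; else lo = m; }
    return lo;
  }
  static int find_window(const std::vector<double> &c, const std::vector<double> &h,
                         double v) {
    int lo = 0, hi = (int)c.size() - 1, best = -1;
    while (lo <= hi) {
      int m = (lo + hi) / 2;
      if (v < c[m] - h[m]) hi = m - 1;
      else if (v > c[m] + h[m]) lo = m + 1;
      else { best = m; break; }
    }
    return best;
  }
  int bin_of(double x, double y, double z) const {
    double r = std::sqrt(x * x + y * y + z * z);
    if (r <= 0.0) return -1;
    double th = std::acos(std::max(-1.0, std::min(1.0, z / r))) * 57.29577951308232;
    int ir, it;
    if (window) { ir = find_window(r_c, r_h, r); it = find_window(th_c, th_h, th); }
    else { ir = find_edge(r_edges, r); it = find_edge(th_edges, th); }
    if (ir < 0 || it < 0) return -1;
    return ir * nth + it;
  }
  // returns true if scored
  bool add(double x, double y, double z, double e, bool in_phantom) {
    int b = bin_of(x, y, z);
    if (b < 0) {
      if (in_phantom) gap_e += e; else outside_e += e;
      return false;
    }
    cur[b] += e;
    return true;
  }
  void flush(int batch) {
    if (batch < 0 || batch >= nbatch) return;
    double *dst = &bsum[(size_t)batch * nbin];
    for (int i = 0; i < nbin; ++i) { dst[i] += cur[i]; cur[i] = 0.0; }
  }
};
static Tally parse_tally(const List &tl) {
  Tally t;
  t.window = as<bool>(tl["window"]);
  if (t.window) {
    t.r_c = as<std::vector<double> >(tl["r_centers"]);
    t.r_h = as<std::vector<double> >(tl["r_half"]);
    t.th_c = as<std::vector<double> >(tl["th_centers"]);
    t.th_h = as<std::vector<double> >(tl["th_half"]);
    t.nr = (int)t.r_c.size(); t.nth = (int)t.th_c.size();
  } else {
    t.r_edges = as<std::vector<double> >(tl["r_edges"]);
    t.th_edges = as<std::vector<double> >(tl["th_edges"]);
    t.nr = (int)t.r_edges.size() - 1; t.nth = (int)t.th_edges.size() - 1;
  }
  if (t.window) {
    t.rmax = 0.0;
    for (size_t i = 0; i < t.r_c.size(); ++i)
      t.rmax = std::max(t.rmax, t.r_c[i] + t.r_h[i]);
  } else {
    t.rmax = t.r_edges.back();
  }
  t.nbin = t.nr * t.nth;
  t.nbatch = as<int>(tl["nbatch"]);
  t.cur.assign(t.nbin, 0.0);
  t.bsum.assign((size_t)t.nbin * t.nbatch, 0.0);
  t.gap_e = t.outside_e = 0.0;
  t.score_mode = as<int>(tl["score_mode"]);
  t.medium = as<int>(tl["medium"]);
  return t;
}

// ------------------------------------------------------------- transport --
struct Cfg {
  double cutoff, chard, range_frac, terminal_range, sec_range2;
  bool fluor, secondaries, primary_only, rayleigh;
  int max_segments;
};
static Cfg parse_cfg(const List &cl) {
  Cfg c;
  c.cutoff = cl["cutoff"]; c.chard = cl["chard"]; c.range_frac = cl["range_frac"];
  c.terminal_range = cl["terminal_range"];
  double sr = cl["secondary_range"];
  c.sec_range2 = std::isfinite(sr) ? sr * sr : 1e300;
  c.fluor = as<bool>(cl["fluorescence"]);
  c.secondaries = as<bool>(cl["secondaries"]);
  c.primary_only = as<bool>(cl["primary_only"]);
  c.rayleigh = as<bool>(cl["rayleigh"]);
  c.max_segments = as<int>(cl["max_segments"]);
  return c;
}

struct Counters {
  double emitted = 0, deposited = 0, escaped = 0;
  double e_path = 0;             // total electron path length, cm
  long n_pe = 0, n_compton = 0, n_rayleigh = 0;
  long aborted = 0, ledger_fail = 0;
  long n_scored_events = 0;
};

static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double uz2 = uz * uz;
  if (uz2 > 0.99999999) {  // nearly along z
    double sgn = uz > 0 ? 1.0 : -1.0;
    ux = sint * cphi; uy = sint * sphi; uz = sgn * cost;
    if (sgn < 0) { ux = -ux; uy = -uy; }
    return;
  }
  double sz = std::sqrt(1.0 - uz2);
  double nx = ux * cost + sint * (ux * uz * cphi - uy * sphi) / sz;
  double ny = uy * cost + sint * (uy * uz * cphi + ux * sphi) / sz;
  double nz = uz * cost - sint * sz * cphi;
  double nrm = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx * nrm; uy = ny * nrm; uz = nz * nrm;
}

static const double MEC2 = 510.99895;

// Klein-Nishina sampling of the scattered-photon energy fraction and angle
static inline void sample_kn(Rng &rng, double E, double &eps, double &cost) {
  double k = E / MEC2;
  double emin = 1.0 / (1.0 + 2.0 * k);
  double a1 = std::log(1.0 / emin), a2 = 0.5 * (1.0 - emin * emin);
  for (;;) {
    if (rng.u() * (a1 + a2) < a1) eps = emin * std::exp(a1 * rng.u());
    else eps = std::sqrt(emin * emin + (1.0 - emin * emin) * rng.u());
    double t = (1.0 - eps) / (k * eps);
    double sin2 = t * (2.0 - t);
    double g = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.u() <= g) { cost = 1.0 - t; return; }
  }
}

// Rayleigh angle: inversion on the cumulative F^2(s^2) table + (1+mu^2)/2
static inline double sample_rayleigh_mu(Rng &rng, const Phys &ph, int m, double E) {
  const double HC = 12.398419843320026;  // keV * Angstrom
  double lam = HC / E;
  double xmax = 1.0 / (lam * lam);       // s^2 at mu = -1: s = 1/lambda
  int nx = ph.ray_x.size();
  // cumulative value at xmax
  int ihi = nx - 1;
  while (ihi > 0 && ph.ray_x[ihi - 1] >= xmax) --ihi;
  double cmax;
  if (ihi == 0) cmax = ph.ray_cdf(0, m);
  else {
    double x0 = ph.ray_x[ihi - 1], x1 = ph.ray_x[ihi];
    double f = (xmax - x0) / (x1 - x0);
    if (f > 1.0) f = 1.0;
    cmax = ph.ray_cdf(ihi - 1, m) + f * (ph.ray_cdf(ihi, m) - ph.ray_cdf(ihi - 1, m));
  }
  for (int iter = 0; iter < 1000; ++iter) {
    double target = rng.u() * cmax;
    int lo = 0, hi = nx - 1;
    while (hi - lo > 1) { int mm = (lo + hi) / 2;
      if (ph.ray_cdf(mm, m) < target) lo = mm; else hi = mm; }
    double c0 = ph.ray_cdf(lo, m), c1 = ph.ray_cdf(hi, m);
    double f = (c1 > c0) ? (target - c0) / (c1 - c0) : 0.0;
    double x = ph.ray_x[lo] + f * (ph.ray_x[hi] - ph.ray_x[lo]);
    if (x > xmax) x = xmax;
    double mu = 1.0 - 2.0 * x * lam * lam;
    if (mu < -1.0) mu = -1.0;
    if (rng.u() <= 0.5 * (1.0 + mu * mu)) return mu;
  }
  return 1.0;
}

// condensed-history electron; deposits energy along the track.
// Dose is scored only for deposits in the phantom region (the published
// aggregation region excludes the source assembly); elsewhere the deposit
// only enters the energy ledger.
static void electron_history(const Geom &g, const Phys &ph, const Cfg &cfg,
                             Rng &rng, Tally &tl, Counters &cnt,
                             double E, double px, double py, double pz,
                             double ux, double uy, double uz, int region,
                             double &dep, double &esc) {
  int nseg = 0;
  bool score = (tl.score_mode == 0);
  double safety = -1.0;   // invalid: recompute
  auto deposit = [&](double x, double y, double z, double e, int reg) {
    if (e <= 0.0) return;
    if (score) {
      if (reg == R_PHANTOM) tl.add(x, y, z, e, true);
      else tl.outside_e += e;
    }
    dep += e;
  };
  while (true) {
    if (region == R_OUTSIDE) { esc += E; return; }
    if (E < cfg.cutoff) break;
    if (++nseg > cfg.max_segments) { cnt.aborted++; dep += E; return; }
    int m = g.material_at(px, py, pz, region);
    double rho = ph.rho[m];
    if (rho <= 0.0) {  // vacuum: free flight to the boundary
      double db = boundary_distance(g, px, py, pz, ux, uy, uz, region);
      double adv = db + EPS_NUDGE;
      px += adv * ux; py += adv * uy; pz += adv * uz;
      region = g.locate(px, py, pz);
      safety = -1.0;
      continue;
    }
    double Rcm = ph.look(ph.csda, E, m) / rho;          // residual range, cm
    if (safety < 0.0) safety = safety_distance(g, px, py, pz, region);
    // range rejection: the track cannot leave the region
    if (Rcm < safety &&
        (region != R_PHANTOM || Rcm < cfg.terminal_range)) {
      deposit(px, py, pz, E, region);
      return;
    }
    double S = ph.look(ph.scol, E, m) * 1000.0 * rho;   // keV/cm
    double step = cfg.chard;
    if (cfg.range_frac * Rcm < step) step = cfg.range_frac * Rcm;
    bool hit = false;
    if (safety <= step) {  // near a boundary: fall back to ray tracing
      double db = boundary_distance(g, px, py, pz, ux, uy, uz, region);
      if (db <= step) { step = db; hit = true; }
      safety = -1.0;
    } else {
      safety -= step;
    }
    double dE = S * step;
    if (dE >= E) { dE = E; step = E / S; hit = false; }
    deposit(px + 0.5 * step * ux, py + 0.5 * step * uy,
            pz + 0.5 * step * uz, dE, region);
    cnt.e_path += step;
    E -= dE;
    double adv = hit ? step + EPS_NUDGE : step;
    px += adv * ux; py += adv * uy; pz += adv * uz;
    if (hit) {
      int nreg = g.locate(px, py, pz);
      if (nreg != region) { region = nreg; safety = -1.0; }
      continue;
    }
    if (E < cfg.cutoff) break;
    // Highland multiple-scattering hinge; the space angle of two iid
    // Gaussian projected angles is Rayleigh distributed
    double pc2 = E * (E + 2.0 * MEC2);                  // (pc)^2, keV^2
    double beta_pc = pc2 / (E + MEC2);                  // beta * pc, keV
    double trl = step * rho / ph.x0[m];                 // radiation lengths
    if (trl > 0.0) {
      double lt = std::log(trl);
      double th0 = 13600.0 / beta_pc * std::sqrt(trl) * (1.0 + 0.038 * lt);
      if (th0 > 0.0) {
        double ths = th0 * std::sqrt(-2.0 * std::log(rng.uo()));
        if (ths > 1.5) ths = 1.5;   // cap pathological tails
        rotate_dir(ux, uy, uz, std::cos(ths), 6.283185307179586 * rng.u());
      }
    }
  }
  deposit(px, py, pz, E, region);  // residual below cutoff
}


// track-length (expected collision kerma) scoring of a flight segment:
// contribution E * (mu_tr/rho) * rho per unit path, deposited along the
// segment clipped to the tally's radial extent, in sub-steps no longer
// than half the narrowest bin dimension used here (0.02 cm)
static void score_track_kerma(Tally &tl, const Phys &ph, int m, double rho,
                              double E, double px, double py, double pz,
                              double ux, double uy, double uz, double seg) {
  if (rho <= 0.0 || seg <= 0.0) return;
  double wpc = E * ph.look(ph.mutr, E, m) * rho;   // keV per cm of track
  if (wpc <= 0.0) return;
  // clip [0, seg] to r(t) <= rmax
  double c = px * px + py * py + pz * pz - tl.rmax * tl.rmax;
  double b = px * ux + py * uy + pz * uz;
  double disc = b * b - c;
  if (disc <= 0.0) return;                         // never inside rmax
  double sq = std::sqrt(disc);
  double ta = std::max(0.0, -b - sq), tb = std::min(seg, -b + sq);
  if (tb <= ta) return;
  int nsub = (int)((tb - ta) / 0.02) + 1;
  double ds = (tb - ta) / nsub;
  for (int i = 0; i < nsub; ++i) {
    double t = ta + (i + 0.5) * ds;
    tl.add(px + t * ux, py + t * uy, pz + t * uz, wpc * ds, true);
  }
}

// rng: primary-photon stream; rng2: stream for secondary particles
// (recoil/photo-electrons and fluorescence photons), so that their variable
// draw counts cannot desynchronize the primary stream between paired runs
static void photon_history(const Geom &g, const Phys &ph, const Cfg &cfg,
                           Rng &rng, Rng &rng2, Tally &tl, Counters &cnt,
                           double E0, double px0, double py0, double pz0,
                           double ux0, double uy0, double uz0,
                           double &dep, double &esc) {
  // small stack: primary + fluorescence photons
  const int NST = 8;
  double stE[NST], stx[NST], sty[NST], stz[NST], stux[NST], stuy[NST], stuz[NST];
  bool stsec[NST];
  int nst = 0;
  stE[0] = E0; stx[0] = px0; sty[0] = py0; stz[0] = pz0;
  stux[0] = ux0; stuy[0] = uy0; stuz[0] = uz0; stsec[0] = false; nst = 1;
  bool dose_mode = (tl.score_mode == 0);
  // dose is scored only in the phantom region (the aggregation region
  // excludes the source assembly); deposits elsewhere enter the ledger
  auto deposit = [&](double x, double y, double z, double e, int reg) {
    if (e <= 0.0) return;
    if (dose_mode) {
      if (reg == R_PHANTOM) tl.add(x, y, z, e, true);
      else tl.outside_e += e;
    }
    dep += e;
  };
  while (nst > 0) {
    --nst;
    double E = stE[nst], px = stx[nst], py = sty[nst], pz = stz[nst];
    double ux = stux[nst], uy = stuy[nst], uz = stuz[nst];
    Rng &cr = stsec[nst] ? rng2 : rng;
    int region = g.locate(px, py, pz);
    int nseg = 0;
    // optical-depth marching: one exponential draw per flight, consumed
    // across region boundaries (keeps the random-number consumption
    // independent of the boundary structure, so that paired runs of two
    // designs stay synchronized history by history)
    double tau = -1.0;
    while (true) {
      if (region == R_OUTSIDE) { esc += E; break; }
      if (E < cfg.cutoff) {  // below cutoff: local deposit
        deposit(px, py, pz, E, region);
        break;
      }
      if (++nseg > cfg.max_segments) { cnt.aborted++; dep += E; break; }
      if (tau < 0.0) tau = -std::log(cr.uo());
      int m = g.material_at(px, py, pz, region);
      double rho = ph.rho[m];
      double db = boundary_distance(g, px, py, pz, ux, uy, uz, region);
      double mu = (rho > 0.0) ? ph.look(ph.tot, E, m) * rho : 0.0;
      double s = (mu > 0.0) ? tau / mu : INF_D;
      if (s >= db) {  // cross to next region (or internal surface)
        double adv = db + EPS_NUDGE;
        if (tl.score_mode == 2 && m == tl.medium)
          score_track_kerma(tl, ph, m, rho, E, px, py, pz, ux, uy, uz, db);
        tau -= db * mu;
        if (tau < 0.0) tau = 0.0;
        px += adv * ux; py += adv * uy; pz += adv * uz;
        region = g.locate(px, py, pz);
        continue;
      }
      // interact at distance s
      tau = -1.0;
      if (tl.score_mode == 2 && m == tl.medium)
        score_track_kerma(tl, ph, m, rho, E, px, py, pz, ux, uy, uz, s);
      px += s * ux; py += s * uy; pz += s * uz;
      double xpe = ph.look(ph.pe, E, m), xin = ph.look(ph.incoh, E, m),
             xco = ph.look(ph.coh, E, m);
      double xs = (xpe + xin + xco) * cr.u();
      if (cfg.primary_only) {  // record the process, then stop the history
        if (xs < xpe) cnt.n_pe++;
        else if (xs < xpe + xin) cnt.n_compton++;
        else cnt.n_rayleigh++;
        deposit(px, py, pz, E, region);
        break;
      }
      if (xs < xpe) {  // ------------------------------------ photoelectric
        cnt.n_pe++;
        double e_fluor = 0.0, e_electron = E, local = 0.0;
        if (ph.fl_edge[m] > 0.0 && E > ph.fl_edge[m]) {
          e_electron = E - ph.fl_edge[m];
          local = ph.fl_edge[m];
          if (cfg.fluor && cr.u() < ph.fl_pemit[m]) {
            double u = cr.u();
            int li = (u <= ph.fl_cp(0, m)) ? 0 : (u <= ph.fl_cp(1, m) ? 1 : 2);
            e_fluor = ph.fl_e(li, m);
            local -= e_fluor;
          }
        }
        if (tl.score_mode == 1 && m == tl.medium) {
          tl.add(px, py, pz, E - e_fluor, true);
          cnt.n_scored_events++;
        }
        if (cfg.secondaries && tl.score_mode == 0 &&
            px * px + py * py + pz * pz <= cfg.sec_range2) {
          deposit(px, py, pz, local, region);
          double cu = 2.0 * cr.u() - 1.0,
                 phi = 6.283185307179586 * cr.u();
          double su = std::sqrt(1.0 - cu * cu);
          electron_history(g, ph, cfg, rng2, tl, cnt, e_electron,
                           px, py, pz, su * std::cos(phi), su * std::sin(phi), cu,
                           region, dep, esc);
        } else {
          deposit(px, py, pz, e_electron + local, region);
        }
        if (e_fluor >= cfg.cutoff && nst < NST) {
          double cu = 2.0 * cr.u() - 1.0, phi = 6.283185307179586 * cr.u();
          double su = std::sqrt(1.0 - cu * cu);
          stE[nst] = e_fluor; stx[nst] = px; sty[nst] = py; stz[nst] = pz;
          stux[nst] = su * std::cos(phi); stuy[nst] = su * std::sin(phi);
          stuz[nst] = cu; stsec[nst] = true; ++nst;
        } else if (e_fluor > 0.0) {
          deposit(px, py, pz, e_fluor, region);
        }
        break;  // photon absorbed
      } else if (xs < xpe + xin) {  // --------------------------- Compton
        cnt.n_compton++;
        double eps, cost;
        sample_kn(cr, E, eps, cost);
        double Esc = eps * E, Ee = E - Esc;
        if (tl.score_mode == 1 && m == tl.medium) {
          tl.add(px, py, pz, Ee, true);
          cnt.n_scored_events++;
        }
        // recoil electron
        if (Ee > 0.0) {
          if (cfg.secondaries && tl.score_mode == 0 && Ee >= cfg.cutoff &&
              px * px + py * py + pz * pz <= cfg.sec_range2) {
            double pc_e = std::sqrt(Ee * (Ee + 2.0 * MEC2));
            double ce = (E - Esc * cost) / pc_e;
            if (ce > 1.0) ce = 1.0; if (ce < -1.0) ce = -1.0;
            double ex = ux, ey = uy, ez = uz;
            double phi_e = 6.283185307179586 * cr.u();
            rotate_dir(ex, ey, ez, ce, phi_e);
            electron_history(g, ph, cfg, rng2, tl, cnt, Ee, px, py, pz,
                             ex, ey, ez, region, dep, esc);
            // scattered photon azimuth opposite the electron
            rotate_dir(ux, uy, uz, cost, phi_e + 3.141592653589793);
          } else {
            deposit(px, py, pz, Ee, region);
            rotate_dir(ux, uy, uz, cost, 6.283185307179586 * cr.u());
          }
        } else {
          rotate_dir(ux, uy, uz, cost, 6.283185307179586 * cr.u());
        }
        E = Esc;
        if (E < cfg.cutoff) {
          deposit(px, py, pz, E, region);
          break;
        }
      } else {  // ------------------------------------------------ Rayleigh
        cnt.n_rayleigh++;
        // no energy transfer; kerma contribution zero
        double mu_r = cfg.rayleigh ? sample_rayleigh_mu(cr, ph, m, E) : 1.0;
        rotate_dir(ux, uy, uz, mu_r, 6.283185307179586 * cr.u());
      }
    }
  }
}

// sample a point uniformly inside the active core; uses unit-cylinder
// rejection so that paired runs of the two designs consume identical draws
static inline void sample_core_point(const Geom &g, Rng &rng,
                                     double &x, double &y, double &z) {
  for (;;) {
    double a, b;
    do { a = 2.0 * rng.u() - 1.0; b = 2.0 * rng.u() - 1.0; } while (a * a + b * b > 1.0);
    double zz = 2.0 * rng.u() - 1.0;
    x = a * g.rcore; y = b * g.rcore; z = zz * g.hcore;
    if (g.in_core(x, y, z)) return;
  }
}

// ---------------------------------------------------------- R interface ---

// [[Rcpp::export(name = ".cpp_locate")]]
IntegerVector cpp_locate(List geom, NumericMatrix pts) {
  Geom g = parse_geom(geom);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.locate(pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export(name = ".cpp_distance")]]
List cpp_distance(List geom, NumericVector p, NumericVector u) {
  Geom g = parse_geom(geom);
  int reg = g.locate(p[0], p[1], p[2]);
  // march across internal construction surfaces until the region changes
  double x = p[0], y = p[1], z = p[2], total = 0.0;
  int nxt = reg;
  for (int k = 0; k < 256; ++k) {
    double d = boundary_distance(g, x, y, z, u[0], u[1], u[2], reg);
    if (d >= INF_D) { total = d; nxt = R_OUTSIDE; break; }
    total += d + EPS_NUDGE;
    x = p[0] + total * u[0]; y = p[1] + total * u[1]; z = p[2] + total * u[2];
    nxt = g.locate(x, y, z);
    if (nxt != reg) break;
  }
  return List::create(_["distance"] = total, _["region"] = reg,
                      _["next_region"] = nxt);
}

// [[Rcpp::export(name = ".cpp_sample_core")]]
NumericMatrix cpp_sample_core(List geom, int n, double seed) {
  Geom g = parse_geom(geom);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Rng rng; rng.seed((uint64_t)seed, (uint64_t)i);
    double x, y, z;
    sample_core_point(g, rng, x, y, z);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sample_spectrum")]]
NumericVector cpp_sample_spectrum(List spect, int n, double seed) {
  Spect s = parse_spect(spect);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Rng rng; rng.seed((uint64_t)seed, (uint64_t)i);
    out[i] = s.sample(rng);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sample_kn")]]
NumericMatrix cpp_sample_kn(double E, int n, double seed) {
  NumericMatrix out(n, 2);
  Rng rng; rng.seed((uint64_t)seed, 0);
  for (int i = 0; i < n; ++i) {
    double eps, cost;
    sample_kn(rng, E, eps, cost);
    out(i, 0) = eps; out(i, 1) = cost;
  }
  return out;
}

// main entry: transport histories [i0, i1) of a run of n_total histories
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List geom, List phys, List spect, List tally, List config,
             double n_total, double i0, double i1, double seed,
             int particle) {
  Geom g = parse_geom(geom);
  Phys ph = parse_phys(phys);
  Spect sp = parse_spect(spect);
  Tally tl = parse_tally(tally);
  Cfg cfg = parse_cfg(config);
  Counters cnt;
  long long I0 = (long long)i0, I1 = (long long)i1, N = (long long)n_total;
  int nbatch = tl.nbatch;
  long long cur_batch = -1;
  for (long long i = I0; i < I1; ++i) {
    long long b = i * (long long)nbatch / N;
    if (b != cur_batch) {
      if (cur_batch >= 0) tl.flush((int)cur_batch);
      cur_batch = b;
    }
    Rng rng; rng.seed((uint64_t)seed, (uint64_t)i);
    Rng rng2; rng2.seed((uint64_t)seed ^ 0xA5A5A5A5A5A5A5A5ULL, (uint64_t)i);
    double x, y, z;
    sample_core_point(g, rng, x, y, z);
    double cu = 2.0 * rng.u() - 1.0, phi = 6.283185307179586 * rng.u();
    double su = std::sqrt(1.0 - cu * cu);
    double ux = su * std::cos(phi), uy = su * std::sin(phi), uz = cu;
    double E = sp.sample(rng);
    double dep = 0.0, esc = 0.0;
    if (particle == 0)
      photon_history(g, ph, cfg, rng, rng2, tl, cnt, E, x, y, z, ux, uy, uz, dep, esc);
    else {
      int region = g.locate(x, y, z);
      electron_history(g, ph, cfg, rng, tl, cnt, E, x, y, z, ux, uy, uz,
                       region, dep, esc);
    }
    cnt.emitted += E; cnt.deposited += dep; cnt.escaped += esc;
    if (tl.score_mode == 0 &&
        std::fabs(E - dep - esc) > 1e-9 * std::max(E, 1.0)) cnt.ledger_fail++;
    if (!std::isfinite(dep) || !std::isfinite(esc)) cnt.aborted++;
  }
  tl.flush((int)cur_batch);
  return List::create(
    _["bsum"] = NumericVector(tl.bsum.begin(), tl.bsum.end()),
    _["nr"] = tl.nr, _["nth"] = tl.nth,
    _["gap_energy"] = tl.gap_e, _["outside_energy"] = tl.outside_e,
    _["emitted"] = cnt.emitted, _["deposited"] = cnt.deposited,
    _["escaped"] = cnt.escaped,
    _["n_pe"] = (double)cnt.n_pe, _["n_compton"] = (double)cnt.n_compton,
    _["n_rayleigh"] = (double)cnt.n_rayleigh,
    _["aborted"] = (double)cnt.aborted,
    _["ledger_fail"] = (double)cnt.ledger_fail,
    _["e_path"] = cnt.e_path,
    _["n_histories"] = (double)(I1 - I0));
}
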