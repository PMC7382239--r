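// Core fixed-time-step engine for confined microtubule self-organization.
//
// Microtubules are chains of fixed-length elements confined to a convex
// domain.  Per step: diffuse nucleation, plus-end dynamic instability,
// boundary deflection/edge catastrophe, angle-dependent collision rules
// (bundling / induced catastrophe / crossover), and Bernoulli severing of
// registered crossovers.  All randomness flows through one mt19937_64
// stream per engine so identical seeds give bit-identical trajectories.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>

namespace {

constexpr double kPi = 3.14159265358979323846;
constexpr double kGeomTol = 1e-9;

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// --------------------------------------------------------------------------
// Domain: convex confining region centered at the origin.
// kind: 0 sphere (radius a), 1 box (Lx=a, Ly=b, Lz=c),
//       2 triangular prism (equilateral side a, height c, one side || +x),
//       3 cylinder (radius a, height c, axis z).
struct Domain {
  int kind;
  double a, b, c;

  bool contains(const Vec3 &p) const {
    switch (kind) {
      case 0:
        return norm(p) <= a + kGeomTol;
      case 1:
        return std::fabs(p.x) <= 0.5 * a + kGeomTol &&
               std::fabs(p.y) <= 0.5 * b + kGeomTol &&
               std::fabs(p.z) <= 0.5 * c + kGeomTol;
      case 2: {
        if (std::fabs(p.z) > 0.5 * c + kGeomTol) return false;
        // equilateral triangle, centroid at origin, base at y = -H/3
        double H = a * std::sqrt(3.0) / 2.0;
        if (p.y < -H / 3.0 - kGeomTol) return false;
        // slanted sides: inward half-planes through (±a/2, -H/3) and (0, 2H/3)
        // right side inward normal: (-sqrt(3)/2, -1/2); left mirrored
        double dr = -std::sqrt(3.0) / 2.0 * (p.x - 0.5 * a) - 0.5 * (p.y + H / 3.0);
        double dl = std::sqrt(3.0) / 2.0 * (p.x + 0.5 * a) - 0.5 * (p.y + H / 3.0);
        return dr >= -kGeomTol && dl >= -kGeomTol;
      }
      case 3:
        return std::sqrt(p.x * p.x + p.y * p.y) <= a + kGeomTol &&
               std::fabs(p.z) <= 0.5 * c + kGeomTol;
    }
    return false;
  }

  // Outward unit normal of the face nearest to a (near-)boundary point.
  Vec3 outwardNormal(const Vec3 &p) const {
    switch (kind) {
      case 0:
        return normalize(p);
      case 1: {
        double dx = 0.5 * a - std::fabs(p.x);
        double dy = 0.5 * b - std::fabs(p.y);
        double dz = 0.5 * c - std::fabs(p.z);
        if (dx <= dy && dx <= dz) return {p.x >= 0 ? 1.0 : -1.0, 0, 0};
        if (dy <= dz) return {0, p.y >= 0 ? 1.0 : -1.0, 0};
        return {0, 0, p.z >= 0 ? 1.0 : -1.0};
      }
      case 2: {
        double H = a * std::sqrt(3.0) / 2.0;
        double dz = 0.5 * c - std::fabs(p.z);
        double db = p.y + H / 3.0;
        double dr = -std::sqrt(3.0) / 2.0 * (p.x - 0.5 * a) - 0.5 * (p.y + H / 3.0);
        double dl = std::sqrt(3.0) / 2.0 * (p.x + 0.5 * a) - 0.5 * (p.y + H / 3.0);
        double dmin = std::min(std::min(db, dz), std::min(dr, dl));
        if (dz == dmin) return {0, 0, p.z >= 0 ? 1.0 : -1.0};
        if (db == dmin) return {0, -1, 0};
        if (dr == dmin) return {std::sqrt(3.0) / 2.0, 0.5, 0};
        return {-std::sqrt(3.0) / 2.0, 0.5, 0};
      }
      case 3: {
        double rho = std::sqrt(p.x * p.x + p.y * p.y);
        double dz = 0.5 * c - std::fabs(p.z);
        if (a - rho <= dz && rho > kGeomTol)
          return {p.x / rho, p.y / rho, 0};
        return {0, 0, p.z >= 0 ? 1.0 : -1.0};
      }
    }
    return {0, 0, 1};
  }

  // First boundary crossing of the ray p + t*dir, t in (0, step].
  // Returns false when the full step stays inside (convexity makes the
  // inside interval connected, so bisection on containment is exact).
  bool boundaryHit(const Vec3 &p, const Vec3 &dir, double step,
                   Vec3 &hit, Vec3 &nrm, double &incidence_deg) const {
    if (contains(p + step * dir)) return false;
    double lo = 0.0, hi = step;
    for (int it = 0; it < 80; ++it) {
      double mid = 0.5 * (lo + hi);
      if (contains(p + mid * dir)) lo = mid; else hi = mid;
    }
    hit = p + lo * dir;
    nrm = outwardNormal(hit);
    double s = dot(dir, nrm);
    if (s < 0) s = 0;
    if (s > 1) s = 1;
    incidence_deg = std::asin(s) * 180.0 / kPi;
    return true;
  }

  // Axis-aligned bounding box (for grids and rejection sampling).
  void bbox(Vec3 &lo, Vec3 &hi) const {
    switch (kind) {
      case 0: lo = {-a, -a, -a}; hi = {a, a, a}; return;
      case 1: lo = {-0.5 * a, -0.5 * b, -0.5 * c}; hi = {0.5 * a, 0.5 * b, 0.5 * c}; return;
      case 2: {
        double H = a * std::sqrt(3.0) / 2.0;
        lo = {-0.5 * a, -H / 3.0, -0.5 * c};
        hi = {0.5 * a, 2.0 * H / 3.0, 0.5 * c};
        return;
      }
      case 3: lo = {-a, -a, -0.5 * c}; hi = {a, a, 0.5 * c}; return;
    }
  }
};

// Project dir into the tangent plane of the boundary; false when head-on.
bool deflectDir(const Vec3 &dir, const Vec3 &nrm, Vec3 &out) {
  Vec3 t = dir - dot(dir, nrm) * nrm;
  double tn = norm(t);
  if (tn < kGeomTol) return false;
  out = (1.0 / tn) * t;
  return true;
}

// --------------------------------------------------------------------------
struct Params {
  double ell;           // element length, um
  double p_spont_cat;   // per-step spontaneous catastrophe (plus end)
  double p_rescue;      // per-step rescue (plus end)
  double p_cat;         // induced catastrophe on steep collision
  double p_cross;       // per-step severing of a registered crossover
  double alpha_deg;     // bundling threshold angle
  double k_nuc;         // expected nucleations per step (Poisson)
  double d_contact;     // contact radius, um
  double p_edge_cat;    // catastrophe prob. on steep/degenerate boundary hit
  double theta_edge_deg;// incidence threshold separating deflection from edge catastrophe
  int nucleation_mode;  // 0 volume, 1 surface
  int minus_shrink_every; // 0 = static minus ends
};

struct MT {
  int id;
  int birth;
  int plus_state;   // 0 growing, 1 shrinking
  int minus_state;  // 0 static, 1 shrinking
  bool alive;
  int start;        // index of first live vertex in v
  std::vector<Vec3> v;

  int nVert() const { return static_cast<int>(v.size()) - start; }
  int nElem() const { return nVert() - 1; }
  // element e (absolute index) spans v[e], v[e+1]; valid for
  // start <= e <= start + nElem() - 1
  bool elemValid(int e) const { return e >= start && e <= start + nElem() - 1; }
};

struct Crossover {
  int cross_mt;   // internal index of the crossing (severable) MT
  int cross_elem; // absolute element index on the crossing MT
  int host_mt;
  int host_elem;
  int created;
  bool live;
};

// Uniform grid over the domain bounding box; elements binned by midpoint.
struct Grid {
  double cell;
  Vec3 lo;
  int nx, ny, nz;
  std::vector<std::vector<int64_t>> bins;
  std::vector<int> touched;

  void init(const Domain &d, double cell_size) {
    Vec3 hi;
    d.bbox(lo, hi);
    cell = cell_size;
    nx = std::max(1, (int)std::ceil((hi.x - lo.x) / cell) + 2);
    ny = std::max(1, (int)std::ceil((hi.y - lo.y) / cell) + 2);
    nz = std::max(1, (int)std::ceil((hi.z - lo.z) / cell) + 2);
    bins.assign((size_t)nx * ny * nz, {});
  }
  int idx(const Vec3 &p) const {
    int ix = (int)std::floor((p.x - lo.x) / cell) + 1;
    int iy = (int)std::floor((p.y - lo.y) / cell) + 1;
    int iz = (int)std::floor((p.z - lo.z) / cell) + 1;
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);
    return (ix * ny + iy) * nz + iz;
  }
  void insert(int mt, int elem, const Vec3 &mid) {
    int i = idx(mid);
    if (bins[i].empty()) touched.push_back(i);
    bins[i].push_back(((int64_t)mt << 32) | (uint32_t)elem);
  }
  void clear() {
    for (int i : touched) bins[i].clear();
    touched.clear();
  }
};

double pointSegDist(const Vec3 &p, const Vec3 &a, const Vec3 &b) {
  Vec3 ab = b - a;
  double t = dot(p - a, ab) / dot(ab, ab);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  return norm(p - (a + t * ab));
}

// --------------------------------------------------------------------------
struct Engine {
  Domain dom;
  Params par;
  std::mt19937_64 rng;
  int step_count = 0;
  int next_id = 0;
  std::vector<MT> mts;
  std::vector<Crossover> xovers;
  Grid grid;
  // per-step event counts:
  // nucleated, extended, bundled, induced_cat, crossover, boundary_deflect,
  // boundary_cat, spont_cat, rescue, severed, died
  std::vector<std::array<int, 11>> events;
  std::array<int, 11> cur{};

  double runif() {
    return (rng() >> 11) * (1.0 / 9007199254740992.0);
  }
  int rpois(double lambda) {
    if (lambda <= 0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= runif(); } while (p > L);
    return k - 1;
  }
  Vec3 risotropic() {
    double z = 2.0 * runif() - 1.0;
    double phi = 2.0 * kPi * runif();
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    return {r * std::cos(phi), r * std::sin(phi), z};
  }
  Vec3 runifInside() {
    Vec3 lo, hi;
    dom.bbox(lo, hi);
    for (int it = 0; it < 10000; ++it) {
      Vec3 p = {lo.x + runif() * (hi.x - lo.x),
                lo.y + runif() * (hi.y - lo.y),
                lo.z + runif() * (hi.z - lo.z)};
      if (dom.contains(p)) return p;
    }
    return {0, 0, 0};
  }
  // Uniform point on the boundary surface by rejection from a thin shell
  // of the bounding box would be biased; instead sample per-kind.
  Vec3 runifSurface() {
    switch (dom.kind) {
      case 0:
        return dom.a * risotropic();
      case 1: {
        double Lx = dom.a, Ly = dom.b, Lz = dom.c;
        double axy = Lx * Ly, axz = Lx * Lz, ayz = Ly * Lz;
        double tot = 2 * (axy + axz + ayz), u = runif() * tot;
        double sx = (runif() - 0.5) * Lx, sy = (runif() - 0.5) * Ly,
               sz = (runif() - 0.5) * Lz, sgn = runif() < 0.5 ? -0.5 : 0.5;
        if (u < 2 * axy) return {sx, sy, sgn * Lz};
        if (u < 2 * (axy + axz)) return {sx, sgn * Ly, sz};
        return {sgn * Lx, sy, sz};
      }
      case 2: {
        double s = dom.a, h = dom.c, H = s * std::sqrt(3.0) / 2.0;
        double atri = std::sqrt(3.0) / 4.0 * s * s, aside = s * h;
        double tot = 2 * atri + 3 * aside, u = runif() * tot;
        if (u < 2 * atri) {
          // uniform in triangle via sqrt trick
          double r1 = std::sqrt(runif()), r2 = runif();
          Vec3 A = {-0.5 * s, -H / 3.0, 0}, B = {0.5 * s, -H / 3.0, 0},
               C = {0, 2 * H / 3.0, 0};
          Vec3 p = (1 - r1) * A + (r1 * (1 - r2)) * B + (r1 * r2) * C;
          p.z = (u < atri) ? 0.5 * h : -0.5 * h;
          return p;
        }
        int side = (int)((u - 2 * atri) / aside);
        double t = runif(), z = (runif() - 0.5) * h;
        Vec3 A, B;
        if (side == 0) { A = {-0.5 * s, -H / 3.0, 0}; B = {0.5 * s, -H / 3.0, 0}; }
        else if (side == 1) { A = {0.5 * s, -H / 3.0, 0}; B = {0, 2 * H / 3.0, 0}; }
        else { A = {0, 2 * H / 3.0, 0}; B = {-0.5 * s, -H / 3.0, 0}; }
        Vec3 p = A + t * (B - A);
        p.z = z;
        return p;
      }
      case 3: {
        double r = dom.a, h = dom.c;
        double acap = kPi * r * r, aside = 2 * kPi * r * h;
        double tot = 2 * acap + aside, u = runif() * tot;
        if (u < 2 * acap) {
          double rr = r * std::sqrt(runif()), phi = 2 * kPi * runif();
          return {rr * std::cos(phi), rr * std::sin(phi),
                  (u < acap) ? 0.5 * h : -0.5 * h};
        }
        double phi = 2 * kPi * runif();
        return {r * std::cos(phi), r * std::sin(phi), (runif() - 0.5) * h};
      }
    }
    return {0, 0, 0};
  }

  void initGrid() {
    double cell = std::max(par.ell, std::max(par.d_contact, 0.5 * par.ell + par.d_contact));
    grid.init(dom, cell);
  }
  void rebuildGrid() {
    grid.clear();
    for (size_t m = 0; m < mts.size(); ++m) {
      const MT &mt = mts[m];
      if (!mt.alive) continue;
      for (int e = mt.start; e <= mt.start + mt.nElem() - 1; ++e)
        grid.insert((int)m, e, 0.5 * (mt.v[e] + mt.v[e + 1]));
    }
  }

  void addMT(const std::vector<Vec3> &verts, int plus_state, int minus_state) {
    MT mt;
    mt.id = next_id++;
    mt.birth = step_count;
    mt.plus_state = plus_state;
    mt.minus_state = minus_state;
    mt.alive = true;
    mt.start = 0;
    mt.v = verts;
    mts.push_back(std::move(mt));
    const MT &ref = mts.back();
    for (int e = 0; e <= ref.nElem() - 1; ++e)
      grid.insert((int)mts.size() - 1, e,
                  0.5 * (ref.v[e] + ref.v[e + 1]));
  }

  void nucleate() {
    int n = rpois(par.k_nuc);
    for (int i = 0; i < n; ++i) {
      Vec3 p0 = (par.nucleation_mode == 0) ? runifInside() : runifSurface();
      Vec3 d{1, 0, 0};
      bool ok = false;
      for (int tries = 0; tries < 200 && !ok; ++tries) {
        d = risotropic();
        if (par.nucleation_mode == 1) {
          // confine the initial heading to the local tangent plane,
          // sliding inward where the tangent chord exits a curved face
          Vec3 nrm = dom.outwardNormal(p0), td;
          if (!deflectDir(d, nrm, td)) continue;
          d = dom.contains(p0 + par.ell * td) ? td : slideInward(p0, td, nrm);
        }
        ok = dom.contains(p0 + par.ell * d);
      }
      if (!ok) continue;
      addMT({p0, p0 + par.ell * d}, 0, par.minus_shrink_every < 0 ? 1 : 0);
      ++cur[0];
    }
  }

  // Tilt dir toward -nrm until the full step lands inside (boundary slide
  // on curved faces keeps element length exact).  Assumes tilting by 90
  // degrees (pure inward normal) is inside.
  Vec3 slideInward(const Vec3 &tip, const Vec3 &dir, const Vec3 &nrm) {
    double lo = 0.0, hi = 0.5 * kPi; // radians of tilt
    auto tilted = [&](double phi) {
      return normalize(std::cos(phi) * dir - std::sin(phi) * nrm);
    };
    if (!dom.contains(tip + par.ell * tilted(hi))) return tilted(hi);
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (dom.contains(tip + par.ell * tilted(mid))) hi = mid; else lo = mid;
    }
    return tilted(hi);
  }

  void dropRecordsForElem(int m, int e) {
    for (auto &x : xovers) {
      if (!x.live) continue;
      if ((x.cross_mt == m && x.cross_elem == e) ||
          (x.host_mt == m && x.host_elem == e))
        x.live = false;
    }
  }
  void dropRecordsForMT(int m) {
    for (auto &x : xovers)
      if (x.live && (x.cross_mt == m || x.host_mt == m)) x.live = false;
  }

  void killMT(int m) {
    mts[m].alive = false;
    dropRecordsForMT(m);
    ++cur[10];
  }

  // Nearest foreign element within d_contact of point p; excludes the
  // growing MT's own most recent kExcl elements. Returns false if none.
  bool nearestContact(int self, const Vec3 &p, int &out_mt, int &out_elem) {
    const int kExcl = 2;
    const MT &sf = mts[self];
    int selfLast = sf.start + sf.nElem() - 1;
    double best = par.d_contact;
    bool found = false;
    int ix = (int)std::floor((p.x - grid.lo.x) / grid.cell) + 1;
    int iy = (int)std::floor((p.y - grid.lo.y) / grid.cell) + 1;
    int iz = (int)std::floor((p.z - grid.lo.z) / grid.cell) + 1;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jx >= grid.nx || jy < 0 || jy >= grid.ny ||
              jz < 0 || jz >= grid.nz)
            continue;
          for (int64_t key : grid.bins[(size_t)(jx * grid.ny + jy) * grid.nz + jz]) {
            int m = (int)(key >> 32);
            int e = (int)(key & 0xffffffff);
            const MT &mt = mts[m];
            if (!mt.alive || !mt.elemValid(e)) continue;
            if (m == self && e > selfLast - kExcl) continue;
            double dd = pointSegDist(p, mt.v[e], mt.v[e + 1]);
            if (dd <= best) {
              // deterministic tie-break: smaller mt index, then element
              if (dd < best || !found ||
                  m < out_mt || (m == out_mt && e < out_elem)) {
                best = dd;
                out_mt = m;
                out_elem = e;
                found = true;
              }
            }
          }
        }
    return found;
  }

  void appendVertex(int m, const Vec3 &p) {
    MT &mt = mts[m];
    mt.v.push_back(p);
    int e = mt.start + mt.nElem() - 1;
    grid.insert(m, e, 0.5 * (mt.v[e] + mt.v[e + 1]));
  }

  void growTip(int mi) {
    MT &mt = mts[mi];
    int last = (int)mt.v.size() - 1;
    Vec3 tip = mt.v[last];
    Vec3 dir = normalize(mt.v[last] - mt.v[last - 1]);

    // --- boundary resolution -------------------------------------------
    bool deflected = false;
    for (int it = 0; it < 8; ++it) {
      Vec3 hit, nrm;
      double inc;
      if (!dom.boundaryHit(tip, dir, par.ell, hit, nrm, inc)) break;
      Vec3 nd;
      bool have_tangent = deflectDir(dir, nrm, nd);
      bool steep = inc >= par.theta_edge_deg || !have_tangent;
      if (steep) {
        if (runif() < par.p_edge_cat || !have_tangent) {
          mt.plus_state = 1;
          ++cur[6];
          return;
        }
      }
      // tangential continuation; slide inward on curved faces
      if (dom.contains(tip + par.ell * nd)) {
        dir = nd;
      } else {
        dir = slideInward(tip, nd, nrm);
      }
      deflected = true;
      if (it == 7 && !dom.contains(tip + par.ell * dir)) {
        mt.plus_state = 1; // cornered: treat as edge catastrophe
        ++cur[6];
        return;
      }
    }
    Vec3 proposed = tip + par.ell * dir;

    // --- contact resolution --------------------------------------------
    int cm, ce;
    if (nearestContact(mi, proposed, cm, ce)) {
      const MT &host = mts[cm];
      Vec3 tdir = normalize(host.v[ce + 1] - host.v[ce]);
      double cosang = std::fabs(dot(dir, tdir));
      if (cosang > 1) cosang = 1;
      double theta = std::acos(cosang) * 180.0 / kPi;
      if (theta < par.alpha_deg) {
        // bundle: adopt host orientation, sign minimizing the turn
        Vec3 nd = (dot(dir, tdir) >= 0) ? tdir : (-1.0 * tdir);
        Vec3 np = tip + par.ell * nd;
        if (!dom.contains(np)) {
          Vec3 hit, nrm;
          double inc;
          if (dom.boundaryHit(tip, nd, par.ell, hit, nrm, inc)) {
            Vec3 td;
            if (deflectDir(nd, nrm, td))
              nd = dom.contains(tip + par.ell * td) ? td
                                                    : slideInward(tip, td, nrm);
            else {
              mt.plus_state = 1;
              ++cur[6];
              return;
            }
          }
          np = tip + par.ell * nd;
          if (!dom.contains(np)) {
            mt.plus_state = 1;
            ++cur[6];
            return;
          }
        }
        appendVertex(mi, np);
        ++cur[2];
        return;
      }
      if (runif() < par.p_cat) {
        mt.plus_state = 1;
        ++cur[3];
        return;
      }
      // crossover: grow through and register a severable crossing
      // (self-crossings grow through but are never severable)
      appendVertex(mi, proposed);
      if (cm == mi) {
        ++cur[4];
        return;
      }
      Crossover x;
      x.cross_mt = mi;
      x.cross_elem = mts[mi].start + mts[mi].nElem() - 1;
      x.host_mt = cm;
      x.host_elem = ce;
      x.created = step_count;
      x.live = true;
      xovers.push_back(x);
      ++cur[4];
      return;
    }

    appendVertex(mi, proposed);
    ++cur[deflected ? 5 : 1];
  }

  void shrinkPlus(int mi) {
    MT &mt = mts[mi];
    int lastElem = mt.start + mt.nElem() - 1;
    dropRecordsForElem(mi, lastElem);
    mt.v.pop_back();
    if (mt.nVert() < 2) killMT(mi);
  }

  void shrinkMinus(int mi) {
    MT &mt = mts[mi];
    dropRecordsForElem(mi, mt.start);
    mt.start += 1;
    if (mt.nVert() < 2) killMT(mi);
  }

  // Split the crossing MT at its cut element.  Elements before the cut stay
  // with the original MT (new plus end, shrinking); the cut element onward
  // becomes a fresh MT whose new minus end shrinks.  Surviving records are
  // re-attached with shifted indices.  Total element count is conserved.
  void sever(size_t xi) {
    Crossover rec = xovers[xi];
    xovers[xi].live = false;
    int m = rec.cross_mt, cut = rec.cross_elem;
    MT &A = mts[m];
    int lastElem = A.start + A.nElem() - 1;

    // fragment B: vertices cut..end
    std::vector<Vec3> bv(A.v.begin() + cut, A.v.end());
    MT B;
    B.id = next_id++;
    B.birth = step_count;
    B.plus_state = A.plus_state;
    B.minus_state = 1;
    B.alive = true;
    B.start = 0;
    B.v = std::move(bv);
    int bIndex = (int)mts.size();

    // fragment A keeps vertices start..cut, plus end now shrinking
    A.v.resize(cut + 1);
    A.plus_state = 1;

    for (auto &x : xovers) {
      if (!x.live) continue;
      if (x.cross_mt == m && x.cross_elem >= cut) {
        x.cross_mt = bIndex;
        x.cross_elem -= cut;
      }
      if (x.host_mt == m && x.host_elem >= cut) {
        x.host_mt = bIndex;
        x.host_elem -= cut;
      }
    }
    mts.push_back(std::move(B));
    if (mts[m].nVert() < 2) killMT(m);
    if (mts[bIndex].nVert() < 2) killMT(bIndex);
    ++cur[9];
  }

  void severingPass() {
    size_t n0 = xovers.size();
    for (size_t i = 0; i < n0; ++i) {
      Crossover &x = xovers[i];
      if (!x.live) continue;
      if (!mts[x.cross_mt].alive || !mts[x.cross_mt].elemValid(x.cross_elem) ||
          !mts[x.host_mt].alive || !mts[x.host_mt].elemValid(x.host_elem)) {
        x.live = false;
        continue;
      }
      if (par.p_cross > 0 && runif() < par.p_cross) sever(i);
    }
    // compact dead records occasionally
    if (xovers.size() > 4096) {
      size_t dead = 0;
      for (auto &x : xovers) dead += !x.live;
      if (dead > xovers.size() / 2) {
        std::vector<Crossover> keep;
        keep.reserve(xovers.size() - dead);
        for (auto &x : xovers)
          if (x.live) keep.push_back(x);
        xovers.swap(keep);
      }
    }
  }

  void step() {
    cur.fill(0);
    nucleate();
    size_t nAtStart = mts.size(); // fragments created mid-step act next step
    for (size_t m = 0; m < nAtStart; ++m) {
      if (!mts[m].alive) continue;
      MT &mt = mts[m];
      bool transitioned = false;
      if (mt.plus_state == 0) {
        if (runif() < par.p_spont_cat) {
          mt.plus_state = 1;
          transitioned = true;
          ++cur[7];
        }
      } else {
        if (runif() < par.p_rescue) {
          mt.plus_state = 0;
          transitioned = true;
          ++cur[8];
        }
      }
      if (!transitioned) {
        if (mt.plus_state == 0) growTip((int)m);
        else shrinkPlus((int)m);
      }
      if (mts[m].alive) {
        if (mts[m].minus_state == 1)
          shrinkMinus((int)m);
        else if (par.minus_shrink_every > 0 &&
                 (step_count + 1) % par.minus_shrink_every == 0)
          shrinkMinus((int)m);
      }
    }
    severingPass();
    rebuildGrid();
    ++step_count;
    events.push_back(cur);
  }
};

Domain domainFromList(Rcpp::List d) {
  Domain dom;
  std::string kind = Rcpp::as<std::string>(d["kind"]);
  Rcpp::NumericVector dims = d["dimensions"];
  if (kind == "sphere") {
    dom.kind = 0; dom.a = dims[0]; dom.b = dom.c = 0;
  } else if (kind == "box") {
    dom.kind = 1; dom.a = dims[0]; dom.b = dims[1]; dom.c = dims[2];
  } else if (kind == "triangular_prism") {
    dom.kind = 2; dom.a = dims[0]; dom.b = 0; dom.c = dims[1];
  } else if (kind == "cylinder") {
    dom.kind = 3; dom.a = dims[0]; dom.b = 0; dom.c = dims[1];
  } else {
    Rcpp::stop("unknown domain kind: %s", kind.c_str());
  }
  return dom;
}

Params paramsFromList(Rcpp::List p) {
  Params q;
  q.ell = Rcpp::as<double>(p["ell"]);
  q.p_spont_cat = Rcpp::as<double>(p["p_spont_cat"]);
  q.p_rescue = Rcpp::as<double>(p["p_rescue"]);
  q.p_cat = Rcpp::as<double>(p["p_cat"]);
  q.p_cross = Rcpp::as<double>(p["p_cross"]);
  q.alpha_deg = Rcpp::as<double>(p["alpha"]);
  q.k_nuc = Rcpp::as<double>(p["k_nuc"]);
  q.d_contact = Rcpp::as<double>(p["d_contact"]);
  q.p_edge_cat = Rcpp::as<double>(p["p_edge_cat"]);
  q.theta_edge_deg = Rcpp::as<double>(p["theta_edge"]);
  std::string nm = Rcpp::as<std::string>(p["nucleation_mode"]);
  q.nucleation_mode = (nm == "surface") ? 1 : 0;
  q.minus_shrink_every = Rcpp::as<int>(p["minus_shrink_every"]);
  return q;
}

}  // namespace

// ===========================================================================

// [[Rcpp::export]]
bool cpp_contains(Rcpp::List domain, Rcpp::NumericVector p) {
  Domain d = domainFromList(domain);
  if (p.size() != 3) Rcpp::stop("point must have 3 coordinates");
  for (int i = 0; i < 3; ++i)
    if (!R_finite(p[i])) Rcpp::stop("non-finite coordinate");
  return d.contains({p[0], p[1], p[2]});
}

// [[Rcpp::export]]
Rcpp::List cpp_boundary_hit(Rcpp::List domain, Rcpp::NumericVector p,
                            Rcpp::NumericVector dir, double step_len) {
  Domain d = domainFromList(domain);
  Vec3 pp{p[0], p[1], p[2]}, dd{dir[0], dir[1], dir[2]};
  if (!d.contains(pp)) Rcpp::stop("start point is outside the domain");
  if (std::fabs(norm(dd) - 1.0) > 1e-6) Rcpp::stop("dir must be a unit vector");
  if (!(step_len > 0)) Rcpp::stop("step_len must be positive");
  Vec3 hit, nrm;
  double inc;
  if (!d.boundaryHit(pp, dd, step_len, hit, nrm, inc))
    return Rcpp::List::create(Rcpp::Named("hit") = false);
  return Rcpp::List::create(
      Rcpp::Named("hit") = true,
      Rcpp::Named("point") = Rcpp::NumericVector::create(hit.x, hit.y, hit.z),
      Rcpp::Named("normal") = Rcpp::NumericVector::create(nrm.x, nrm.y, nrm.z),
      Rcpp::Named("incidence") = inc);
}

// [[Rcpp::export]]
Rcpp::List cpp_deflect(Rcpp::NumericVector dir, Rcpp::NumericVector normal) {
  Vec3 d{dir[0], dir[1], dir[2]}, n{normal[0], normal[1], normal[2]};
  Vec3 out;
  bool ok = deflectDir(d, n, out);
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
  return Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("dir") = Rcpp::NumericVector::create(out.x, out.y, out.z));
}

// [[Rcpp::export]]
SEXP engine_create(Rcpp::List domain, Rcpp::List params, int seed) {
  Engine *e = new Engine();
  e->dom = domainFromList(domain);
  e->par = paramsFromList(params);
  e->rng.seed((uint64_t)seed);
  e->initGrid();
  Rcpp::XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void engine_add_mt(SEXP eng, Rcpp::NumericMatrix vertices, int plus_state,
                   int minus_state) {
  Rcpp::XPtr<Engine> e(eng);
  if (vertices.ncol() != 3 || vertices.nrow() < 2)
    Rcpp::stop("vertices must be an n x 3 matrix with n >= 2");
  std::vector<Vec3> v;
  for (int i = 0; i < vertices.nrow(); ++i) {
    Vec3 p{vertices(i, 0), vertices(i, 1), vertices(i, 2)};
    if (!e->dom.contains(p)) Rcpp::stop("vertex %d lies outside the domain", i + 1);
    v.push_back(p);
  }
  e->addMT(v, plus_state, minus_state);
}

// [[Rcpp::export]]
void engine_register_crossover(SEXP eng, int cross_id, int cross_elem,
                               int host_id, int host_elem) {
  Rcpp::XPtr<Engine> e(eng);
  int cm = -1, hm = -1;
  for (size_t i = 0; i < e->mts.size(); ++i) {
    if (e->mts[i].id == cross_id) cm = (int)i;
    if (e->mts[i].id == host_id) hm = (int)i;
  }
  if (cm < 0 || hm < 0) Rcpp::stop("unknown MT id");
  if (cm == hm) Rcpp::stop("crossing and host MT must differ");
  Crossover x;
  x.cross_mt = cm;
  x.cross_elem = e->mts[cm].start + cross_elem;
  x.host_mt = hm;
  x.host_elem = e->mts[hm].start + host_elem;
  x.created = e->step_count;
  x.live = true;
  if (!e->mts[cm].elemValid(x.cross_elem) || !e->mts[hm].elemValid(x.host_elem))
    Rcpp::stop("element index out of range");
  e->xovers.push_back(x);
}

// [[Rcpp::export]]
void engine_run_steps(SEXP eng, int n) {
  Rcpp::XPtr<Engine> e(eng);
  for (int i = 0; i < n; ++i) {
    e->step();
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
void engine_sever_pass(SEXP eng) {
  Rcpp::XPtr<Engine> e(eng);
  e->cur.fill(0);
  e->severingPass();
  e->events.push_back(e->cur);
}

// [[Rcpp::export]]
int engine_sever_until(SEXP eng, int max_steps) {
  // repeat severing passes until the registry empties; returns the pass
  // index of the severing event, or NA when max_steps is reached
  Rcpp::XPtr<Engine> e(eng);
  for (int t = 1; t <= max_steps; ++t) {
    e->cur.fill(0);
    e->severingPass();
    e->events.push_back(e->cur);
    int live = 0;
    for (auto &x : e->xovers) live += x.live;
    if (live == 0) return t;
  }
  return NA_INTEGER;
}

// [[Rcpp::export]]
Rcpp::List engine_state(SEXP eng) {
  Rcpp::XPtr<Engine> e(eng);
  std::vector<int> alive;
  for (size_t i = 0; i < e->mts.size(); ++i)
    if (e->mts[i].alive) alive.push_back((int)i);
  Rcpp::List mts(alive.size());
  for (size_t k = 0; k < alive.size(); ++k) {
    const MT &mt = e->mts[alive[k]];
    int nv = mt.nVert();
    Rcpp::NumericMatrix v(nv, 3);
    for (int i = 0; i < nv; ++i) {
      v(i, 0) = mt.v[mt.start + i].x;
      v(i, 1) = mt.v[mt.start + i].y;
      v(i, 2) = mt.v[mt.start + i].z;
    }
    mts[k] = Rcpp::List::create(
        Rcpp::Named("id") = mt.id,
        Rcpp::Named("vertices") = v,
        Rcpp::Named("plus_state") = mt.plus_state == 0 ? "growing" : "shrinking",
        Rcpp::Named("minus_state") = mt.minus_state == 0 ? "static" : "shrinking",
        Rcpp::Named("birth_step") = mt.birth);
  }
  int nx = 0;
  for (auto &x : e->xovers) nx += x.live;
  Rcpp::IntegerVector cmt(nx), cel(nx), hmt(nx), hel(nx), cst(nx);
  int j = 0;
  for (auto &x : e->xovers) {
    if (!x.live) continue;
    cmt[j] = e->mts[x.cross_mt].id;
    cel[j] = x.cross_elem - e->mts[x.cross_mt].start;
    hmt[j] = e->mts[x.host_mt].id;
    hel[j] = x.host_elem - e->mts[x.host_mt].start;
    cst[j] = x.created;
    ++j;
  }
  Rcpp::IntegerMatrix ev((int)e->events.size(), 11);
  for (size_t i = 0; i < e->events.size(); ++i)
    for (int c = 0; c < 11; ++c) ev((int)i, c) = e->events[i][c];
  Rcpp::colnames(ev) = Rcpp::CharacterVector::create(
      "nucleated", "extended", "bundled", "induced_catastrophe", "crossover",
      "boundary_deflected", "boundary_catastrophe", "spontaneous_catastrophe",
      "rescue", "severed", "died");
  return Rcpp::List::create(
      Rcpp::Named("step") = e->step_count,
      Rcpp::Named("mts") = mts,
      Rcpp::Named("crossovers") = Rcpp::DataFrame::create(
          Rcpp::Named("crossing_mt_id") = cmt,
          Rcpp::Named("crossing_element_index") = cel,
          Rcpp::Named("host_mt_id") = hmt,
          Rcpp::Named("host_element_index") = hel,
          Rcpp::Named("created_step") = cst),
      Rcpp::Named("events") = ev);
}

// [[Rcpp::export]]
Rcpp::List engine_counts(SEXP eng) {
  Rcpp::XPtr<Engine> e(eng);
  int nmt = 0, nel = 0, nx = 0;
  for (auto &mt : e->mts)
    if (mt.alive) {
      ++nmt;
      nel += mt.nElem();
    }
  for (auto &x : e->xovers) nx += x.live;
  return Rcpp::List::create(Rcpp::Named("step") = e->step_count,
                            Rcpp::Named("n_mts") = nmt,
                            Rcpp::Named("n_elements") = nel,
                            Rcpp::Named("n_crossovers") = nx);
}

// ===========================================================================
// Permutation resampling for the two-sample KS / Kuiper statistics.
namespace {
void ksKuiper(const std::vector<double> &a, const std::vector<double> &b,
              double &D, double &V) {
  // scan the pooled sorted sample; ECDF difference extrema
  size_t n1 = a.size(), n2 = b.size();
  std::vector<std::pair<double, int>> all;
  all.reserve(n1 + n2);
  for (double x : a) all.push_back({x, 0});
  for (double x : b) all.push_back({x, 1});
  std::sort(all.begin(), all.end());
  // integer counts keep the ECDF values exact (k/n), bit-identical to a
  // direct mean(a <= x) evaluation
  size_t ca = 0, cb = 0;
  double dplus = 0, dminus = 0;
  size_t i = 0;
  while (i < all.size()) {
    double x = all[i].first;
    while (i < all.size() && all[i].first == x) {
      if (all[i].second == 0) ++ca; else ++cb;
      ++i;
    }
    double diff = (double)ca / n1 - (double)cb / n2;
    if (diff > dplus) dplus = diff;
    if (-diff > dminus) dminus = -diff;
  }
  D = std::max(dplus, dminus);
  V = dplus + dminus;
}
}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ks_kuiper_stat(Rcpp::NumericVector a,
                                       Rcpp::NumericVector b) {
  std::vector<double> va(a.begin(), a.end()), vb(b.begin(), b.end());
  double D, V;
  ksKuiper(va, vb, D, V);
  return Rcpp::NumericVector::create(Rcpp::Named("D") = D, Rcpp::Named("V") = V);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_perm_stats(Rcpp::NumericVector a, Rcpp::NumericVector b,
                                   int n_perm, std::string method, int seed) {
  size_t n1 = a.size(), n2 = b.size();
  std::vector<double> pool(n1 + n2);
  for (size_t i = 0; i < n1; ++i) pool[i] = a[i];
  for (size_t i = 0; i < n2; ++i) pool[n1 + i] = b[i];
  bool kuiper = (method == "kuiper");
  std::mt19937_64 rng((uint64_t)seed);
  Rcpp::NumericVector out(n_perm);
  std::vector<double> pa(n1), pb(n2);
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates with bounded rejection sampling (unbiased, deterministic)
    for (size_t i = pool.size() - 1; i > 0; --i) {
      uint64_t bound = i + 1;
      uint64_t lim = UINT64_MAX - UINT64_MAX % bound;
      uint64_t r;
      do { r = rng(); } while (r >= lim);
      std::swap(pool[i], pool[r % bound]);
    }
    std::copy(pool.begin(), pool.begin() + n1, pa.begin());
    std::copy(pool.begin() + n1, pool.end(), pb.begin());
    double D, V;
    ksKuiper(pa, pb, D, V);
    out[p] = kuiper ? V : D;
  }
  return out;
}
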