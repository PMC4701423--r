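#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Random walks of a point solute among impenetrable spheres of radius
// r_obs = rho*L/2 centred on the simple cubic lattice L*Z^3, with specular
// reflection at sphere surfaces.  Each walk runs on its own counter-seeded
// xoshiro256++ stream so ensembles are reproducible and order-independent.

namespace {

inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t sm = seed ^ (stream * 0xD1B54A32D192ED03ULL + 0x8CB92BA72F3D8DD7ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double expo(double mean) { return -mean * std::log1p(-unif()); }
  double norm() {  // polar Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has_spare = true;
    return u * f;
  }
  void unit_sphere(double* d) {  // Marsaglia (1972)
    double v1, v2, s2;
    do {
      v1 = 2.0 * unif() - 1.0;
      v2 = 2.0 * unif() - 1.0;
      s2 = v1 * v1 + v2 * v2;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = 2.0 * std::sqrt(1.0 - s2);
    d[0] = v1 * f; d[1] = v2 * f; d[2] = 1.0 - 2.0 * s2;
  }
};

struct Vec { double x, y, z; };
inline Vec operator+(Vec a, Vec b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec operator-(Vec a, Vec b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec operator*(double s, Vec a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec a, Vec b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm2(Vec a) { return dot(a, a); }

// centre of the lattice sphere nearest to p (exact for the cubic lattice)
inline Vec nearest_center(Vec p, double L) {
  return {L * std::nearbyint(p.x / L), L * std::nearbyint(p.y / L),
          L * std::nearbyint(p.z / L)};
}

inline bool inside_sphere(Vec p, double L, double r_obs) {
  if (r_obs <= 0.0) return false;
  return norm2(p - nearest_center(p, L)) < r_obs * r_obs;
}

// Earliest entry parameter s in [0, smax) of ray x + s*u into the sphere at
// centre c (radius r), or -1 if none.  Tangent contact (disc <= 0) counts
// as no collision.
inline double ray_entry(Vec x, Vec u, Vec c, double r, double smax) {
  const Vec w = x - c;
  const double a = norm2(u);
  if (a == 0.0) return -1.0;
  const double b = 2.0 * dot(u, w);
  const double q = norm2(w) - r * r;
  const double disc = b * b - 4.0 * a * q;
  if (disc <= 0.0) return -1.0;
  const double s = (-b - std::sqrt(disc)) / (2.0 * a);
  if (s >= 0.0 && s < smax) return s;
  return -1.0;
}

// Resolve an Euler step start -> start + disp by iterated specular
// reflection: whenever the endpoint lands inside a sphere, the residual
// sub-segment past the ray-sphere entry point is reflected about the
// surface normal.  Returns the final endpoint.
Vec reflect_step(Vec x, Vec disp, double L, double r_obs, int max_reflect,
                 bool* ok) {
  *ok = true;
  if (r_obs <= 0.0) return x + disp;
  Vec y = x + disp;
  int tiny = 0;
  for (int it = 0; it < max_reflect; ++it) {
    const Vec cy = nearest_center(y, L);
    if (norm2(y - cy) >= r_obs * r_obs) return y;
    // candidate first-hit spheres: the one containing y and the one nearest x
    const Vec u = y - x;
    double s = ray_entry(x, u, cy, r_obs, 1.0);
    Vec c = cy;
    const Vec cx = nearest_center(x, L);
    if (cx.x != cy.x || cx.y != cy.y || cx.z != cy.z) {
      const double s2 = ray_entry(x, u, cx, r_obs, 1.0);
      if (s2 >= 0.0 && (s < 0.0 || s2 < s)) { s = s2; c = cx; }
    }
    if (s < 0.0) {
      // roundoff pathology (start on/inside a surface): project the
      // endpoint radially out of its containing sphere and accept
      Vec w = y - cy;
      double d = std::sqrt(norm2(w));
      if (d == 0.0) { w = {1.0, 0.0, 0.0}; d = 1.0; }
      return cy + (r_obs * (1.0 + 1e-12) / d) * w;
    }
    const Vec p = x + s * u;
    Vec nrm = p - c;
    const double nn = std::sqrt(norm2(nrm));
    nrm = (1.0 / nn) * nrm;
    const Vec v = (1.0 - s) * u;
    const Vec vr = v - (2.0 * dot(v, nrm)) * nrm;
    // cusp guard: in the wedge between (near-)touching spheres the chord
    // advance per bounce can shrink towards zero with the residual still
    // finite; once progress stalls the walker is wedged for the rest of
    // this step and is left at the surface (the next step frees it)
    const double advance = s * std::sqrt(norm2(u));
    if (advance < 1e-10 * r_obs) { if (++tiny >= 8) return c + (r_obs * (1.0 + 1e-12)) * nrm; }
    else tiny = 0;
    x = c + (r_obs * (1.0 + 1e-12)) * nrm;  // nudge off the surface
    if (norm2(vr) < 1e-18 * r_obs * r_obs) return x;
    y = x + vr;
  }
  *ok = false;
  return y;
}

// First collision along a straight flight of length smax from x in unit
// direction u; marches in chunks of L/8 so that only the lattice spheres
// nearest the chunk endpoints need to be tested.  Returns hit distance or
// -1 if the flight is free.
double first_hit(Vec x, Vec u, double smax, double L, double r_obs) {
  if (r_obs <= 0.0) return -1.0;
  const double chunk = L / 8.0;
  double s0 = 0.0;
  while (s0 < smax) {
    const double s1 = std::min(s0 + chunk, smax);
    const Vec a = x + s0 * u;
    const Vec bpt = x + s1 * u;
    const Vec ca = nearest_center(a, L);
    const Vec cb = nearest_center(bpt, L);
    double best = -1.0;
    double s = ray_entry(x, u, ca, r_obs, s1);
    if (s >= s0 - 1e-12) best = s;
    if (cb.x != ca.x || cb.y != ca.y || cb.z != ca.z) {
      s = ray_entry(x, u, cb, r_obs, s1);
      if (s >= s0 - 1e-12 && (best < 0.0 || s < best)) best = s;
    }
    if (best >= 0.0) return best;
    s0 = s1;
  }
  return -1.0;
}

Vec draw_start(Rng& rng, int init, double L, double r_obs, bool* ok) {
  *ok = true;
  if (init == 0) return {L / 2.0, L / 2.0, L / 2.0};  // cell body-centre
  for (int tries = 0; tries < 100000; ++tries) {
    Vec p = {L * rng.unif(), L * rng.unif(), L * rng.unif()};
    if (!inside_sphere(p, L, r_obs)) return p;
  }
  *ok = false;
  return {L / 2.0, L / 2.0, L / 2.0};
}

}  // namespace

// [[Rcpp::export]]
List simulate_wiener_cpp(double rho, double L, double D0, int n_walks,
                         int n_record, double t_max, double dt, int init,
                         double seed, int max_reflect, bool record_positions) {
  const double r_obs = rho * L / 2.0;
  const double rec_dt = t_max / (n_record - 1);
  const int m = std::max(1, (int)std::ceil(rec_dt / dt - 1e-9));
  const double dt_a = rec_dt / m;
  const double sigma = std::sqrt(2.0 * D0 * dt_a);
  NumericMatrix sq(n_walks, n_record);
  NumericVector pos;
  if (record_positions) {
    pos = NumericVector(Dimension(3, n_record, n_walks));
  }
  const uint64_t useed = (uint64_t)seed;
  for (int w = 0; w < n_walks; ++w) {
    Rng rng(useed, (uint64_t)w);
    bool ok = true;
    const Vec start = draw_start(rng, init, L, r_obs, &ok);
    if (!ok) stop("could not sample an unobstructed initial position");
    Vec x = start;
    if (record_positions) {
      pos[0 + 3 * (0 + (size_t)n_record * w)] = x.x;
      pos[1 + 3 * (0 + (size_t)n_record * w)] = x.y;
      pos[2 + 3 * (0 + (size_t)n_record * w)] = x.z;
    }
    sq(w, 0) = 0.0;
    for (int k = 1; k < n_record; ++k) {
      for (int s = 0; s < m; ++s) {
        const Vec d = {sigma * rng.norm(), sigma * rng.norm(), sigma * rng.norm()};
        x = reflect_step(x, d, L, r_obs, max_reflect, &ok);
        if (!ok) stop("reflection iteration cap exceeded; reduce dt");
      }
      sq(w, k) = norm2(x - start);
      if (record_positions) {
        pos[0 + 3 * ((size_t)k + (size_t)n_record * w)] = x.x;
        pos[1 + 3 * ((size_t)k + (size_t)n_record * w)] = x.y;
        pos[2 + 3 * ((size_t)k + (size_t)n_record * w)] = x.z;
      }
    }
  }
  NumericVector times(n_record);
  for (int k = 0; k < n_record; ++k) times[k] = k * rec_dt;
  List out = List::create(_["times"] = times, _["sq_disp"] = sq,
                          _["dt_used"] = dt_a);
  if (record_positions) out["positions"] = pos;
  return out;
}

// [[Rcpp::export]]
List simulate_kinetic_cpp(double rho, double L, double D0, double lambda,
                          double tau, int n_walks, int n_record, double t_max,
                          int init, double seed, int max_reflect,
                          bool record_positions) {
  const double r_obs = rho * L / 2.0;
  const double rec_dt = t_max / (n_record - 1);
  NumericMatrix sq(n_walks, n_record);
  NumericVector pos;
  if (record_positions) pos = NumericVector(Dimension(3, n_record, n_walks));
  const uint64_t useed = (uint64_t)seed;
  for (int w = 0; w < n_walks; ++w) {
    Rng rng(useed, (uint64_t)w);
    bool ok = true;
    const Vec start = draw_start(rng, init, L, r_obs, &ok);
    if (!ok) stop("could not sample an unobstructed initial position");
    Vec x = start;
    sq(w, 0) = 0.0;
    if (record_positions) {
      pos[0 + 3 * (0 + (size_t)n_record * w)] = x.x;
      pos[1 + 3 * (0 + (size_t)n_record * w)] = x.y;
      pos[2 + 3 * (0 + (size_t)n_record * w)] = x.z;
    }
    double t_cur = 0.0;
    int k = 1;
    while (k < n_record) {
      const double len = rng.expo(lambda);
      const double dur = rng.expo(tau);
      double dir[3];
      rng.unit_sphere(dir);
      Vec u = {dir[0], dir[1], dir[2]};
      // traverse the (possibly reflected) flight; the step duration is
      // consumed uniformly along the total path length
      double rem = len, done = 0.0;
      int nref = 0;
      while (rem > 0.0) {
        double hit = first_hit(x, u, rem, L, r_obs);
        const double seg = (hit >= 0.0) ? hit : rem;
        // record any sample times falling inside this sub-segment
        while (k < n_record) {
          const double t_rec = k * rec_dt;
          if (t_rec > t_cur + dur || dur <= 0.0) break;
          const double p_rec = (t_rec - t_cur) / dur * len;
          if (p_rec > done + seg + 1e-15) break;
          const double off = std::max(0.0, p_rec - done);
          const Vec xr = x + off * u;
          sq(w, k) = norm2(xr - start);
          if (record_positions) {
            pos[0 + 3 * ((size_t)k + (size_t)n_record * w)] = xr.x;
            pos[1 + 3 * ((size_t)k + (size_t)n_record * w)] = xr.y;
            pos[2 + 3 * ((size_t)k + (size_t)n_record * w)] = xr.z;
          }
          ++k;
        }
        x = x + seg * u;
        done += seg;
        rem -= seg;
        if (hit >= 0.0) {
          if (rem < 1e-9 * L) break;  // negligible cusp residual
          if (++nref > max_reflect) stop("reflection cap exceeded in kinetic flight");
          const Vec c = nearest_center(x, L);
          Vec nrm = x - c;
          const double nn = std::sqrt(norm2(nrm));
          nrm = (1.0 / nn) * nrm;
          u = u - (2.0 * dot(u, nrm)) * nrm;
          x = c + (r_obs * (1.0 + 1e-12)) * nrm;
        }
      }
      t_cur += dur;
    }
  }
  NumericVector times(n_record);
  for (int k2 = 0; k2 < n_record; ++k2) times[k2] = k2 * rec_dt;
  List out = List::create(_["times"] = times, _["sq_disp"] = sq);
  if (record_positions) out["positions"] = pos;
  return out;
}

// [[Rcpp::export]]
NumericVector reflect_segment_cpp(NumericVector start, NumericVector disp,
                                  double r_obs, double L, int max_reflect) {
  const Vec x = {start[0], start[1], start[2]};
  if (inside_sphere(x, L, r_obs))
    stop("segment start lies inside an obstruction");
  const Vec d = {disp[0], disp[1], disp[2]};
  bool ok = true;
  const Vec y = reflect_step(x, d, L, r_obs, max_reflect, &ok);
  if (!ok) stop("reflection iteration cap exceeded");
  return NumericVector::create(y.x, y.y, y.z);
}
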