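// Monte Carlo photon transport in a homogeneous semi-infinite turbid medium.
//
// Geometry: medium occupies z >= 0; a pencil beam enters at the origin going
// +z. Spatially-resolved diffuse reflectance is scored into concentric
// annular rings on the surface. Weighted photons with implicit capture
// (albedo attenuation at every interaction), Henyey-Greenstein scattering,
// Fresnel-tested boundary escape and Russian roulette termination.
//
// The RNG is xoshiro256+ seeded via splitmix64 from a 32-bit seed, so runs
// are bit-reproducible across platforms and independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform double in (0, 1]
  inline double unif_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }
};

inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Unpolarized Fresnel reflection probability for light going n1 -> n2 with
// incidence cosine ci in (0, 1].
inline double fresnel(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export]]
double fresnel_reflectance_cpp(double n1, double n2, double ci) {
  return fresnel(n1, n2, ci);
}

// [[Rcpp::export]]
NumericVector hg_cosine_cpp(double g, NumericVector u) {
  R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = hg_cosine(g, u[i]);
  return out;
}

// [[Rcpp::export]]
List mc_simulate_cpp(double mu_a, double mu_s_prime, double g,
                     double n_medium, double n_above,
                     NumericVector ring_inner_mm, NumericVector ring_outer_mm,
                     double n_photons, double seed,
                     double roulette_threshold = 1e-4,
                     double roulette_survival = 0.1,
                     double kill_radius_mm = 15.0) {
  const int n_rings = ring_inner_mm.size();
  const double mu_s = (g < 1.0) ? mu_s_prime / (1.0 - g) : 0.0;
  const double mu_t = mu_a + mu_s;
  const double albedo = (mu_t > 0.0) ? mu_s / mu_t : 0.0;
  const double frac_abs = (mu_t > 0.0) ? mu_a / mu_t : 0.0;

  // specular loss at normal-incidence entry
  double rsp = 0.0;
  if (n_above != n_medium) {
    double t = (n_above - n_medium) / (n_above + n_medium);
    rsp = t * t;
  }

  std::vector<double> ring_w(n_rings, 0.0);
  double absorbed = 0.0, outside = 0.0, specular = 0.0;
  const long long np = (long long)n_photons;

  Xoshiro rng((uint64_t)(int64_t)seed * 0x9e3779b97f4a7c15ULL + 0x6a09e667f3bcc909ULL);

  for (long long ip = 0; ip < np; ++ip) {
    double w = 1.0 - rsp;
    specular += rsp;
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;

    if (mu_t <= 0.0) {  // transparent medium: ballistic, never returns
      absorbed += w;
      continue;
    }

    bool alive = true;
    while (alive) {
      double s = -std::log(rng.unif_pos()) / mu_t;
      // propagate, handling boundary crossings within the sampled step
      while (true) {
        if (uz < 0.0) {
          double db = -z / uz;  // distance to the z = 0 surface
          if (db <= s) {
            x += ux * db; y += uy * db; z = 0.0;
            s -= db;
            double ci = -uz;
            if (rng.unif() < fresnel(n_medium, n_above, ci)) {
              uz = -uz;  // internal reflection, continue remaining path
              continue;
            }
            // escape: score at exit radius
            double r = std::sqrt(x * x + y * y);
            bool scored = false;
            for (int k = 0; k < n_rings; ++k) {
              if (r >= ring_inner_mm[k] && r < ring_outer_mm[k]) {
                ring_w[k] += w;
                scored = true;
                break;
              }
            }
            if (!scored) outside += w;
            alive = false;
            break;
          }
        }
        x += ux * s; y += uy * s; z += uz * s;
        break;
      }
      if (!alive) break;

      // finite simulation field: photons leaving a sphere of kill_radius_mm
      // around the source cannot meaningfully contribute to the near-source
      // rings and are counted as lost into the bulk
      if (x * x + y * y + z * z > kill_radius_mm * kill_radius_mm) {
        absorbed += w;
        break;
      }

      // interaction: implicit capture then scatter
      absorbed += w * frac_abs;
      w *= albedo;

      if (w < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          // weight gained by survival is balanced against the absorbed tally
          // so each run conserves energy exactly
          double w_new = w / roulette_survival;
          absorbed -= (w_new - w);
          w = w_new;
        } else {
          absorbed += w;
          alive = false;
          break;
        }
      }

      double ct = hg_cosine(g, rng.unif());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 6.283185307179586476925286766559 * rng.unif();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double uxn = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double uyn = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double uzn = -st * cp * den + uz * ct;
        ux = uxn; uy = uyn; uz = uzn;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
  }

  return List::create(
    _["ring_weight"] = NumericVector(ring_w.begin(), ring_w.end()),
    _["escaped_outside"] = outside,
    _["absorbed"] = absorbed,
    _["specular"] = specular,
    _["launched"] = (double)np
  );
}
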