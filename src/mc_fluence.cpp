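// Photon-packet Monte Carlo in a voxelized absorbing/scattering medium.
//
// Continuous absorption weighting: scattering free paths are sampled from
// mu_s alone and the packet weight decays as exp(-mu_a * l) along the path.
// The fluence estimator is the track-length integral of weight per voxel,
// which stays well defined in non-absorbing voxels. Henyey-Greenstein
// scattering, index-matched boundaries (packets leaving the grid escape),
// Russian roulette below a weight threshold.
//
// Randomness comes from an internal xoshiro256++ generator seeded by the
// caller (deterministic given the seed, independent of R's RNG state); the
// per-step call volume makes R's RNG API too slow here.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0 so log() is safe
  inline double u01() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

inline double hg_costheta(double g, Xoshiro256pp &rng) {
  if (g == 0.0) return 2.0 * rng.u01() - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u01());
  return (1.0 + g * g - tmp * tmp) / (2.0 * g);
}

// unit random azimuth (cos, sin) by rejection from the unit disk: avoids
// the per-step trig calls that dominate the scattering loop
inline void rand_azimuth(Xoshiro256pp &rng, double &cp, double &sp) {
  for (;;) {
    double u = 2.0 * rng.u01() - 1.0;
    double v = 2.0 * rng.u01() - 1.0;
    double s2 = u * u + v * v;
    if (s2 > 0.0 && s2 <= 1.0) {
      double inv = 1.0 / s2;
      cp = (u * u - v * v) * inv;
      sp = 2.0 * u * v * inv;
      return;
    }
  }
}

// 1 - exp(-x) with a cheap series for the tiny arguments that dominate here
inline double one_m_exp(double x) {
  if (x < 1e-4) return x * (1.0 - 0.5 * x * (1.0 - x / 3.0));
  return -std::expm1(-x);
}

}  // namespace

// [[Rcpp::export]]
List mc_fluence_cpp(NumericVector mua,      // 1/mm, per voxel (x fastest)
                    NumericVector mus,      // 1/mm, per voxel
                    IntegerVector dims,     // nx, ny, nz
                    double voxel_mm,
                    double g,
                    double beam_radius_mm,
                    double cx_mm, double cy_mm,
                    int n_photons,
                    double roulette_threshold,
                    double roulette_survival,
                    double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dv = voxel_mm, inv_dv = 1.0 / voxel_mm;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mua.size() != nvox || mus.size() != nvox)
    stop("optical property arrays do not match grid dimensions");
  for (R_xlen_t i = 0; i < nvox; ++i)
    if (mua[i] < 0.0 || mus[i] < 0.0 || !R_finite(mua[i]) || !R_finite(mus[i]))
      stop("optical properties must be finite and non-negative");

  NumericVector track(nvox);  // sum of weight * path length (mm) per voxel
  double absorbed = 0.0, escaped = 0.0, killed = 0.0, gained = 0.0;
  const double BIG = 1e30, NUDGE = 1e-7;

  Xoshiro256pp rng((uint64_t)seed);
  for (int ip = 0; ip < n_photons; ++ip) {
    // launch: uniform over a disk on the z = 0 surface, travelling in +z
    double rr = beam_radius_mm * std::sqrt(rng.u01());
    double th = 2.0 * M_PI * rng.u01();
    double x = cx_mm + rr * std::cos(th);
    double y = cy_mm + rr * std::sin(th);
    double z = NUDGE;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    double tau = -std::log(rng.u01());  // remaining scattering optical depth

    for (;;) {
      int ix = (int)std::floor(x * inv_dv);
      int iy = (int)std::floor(y * inv_dv);
      int iz = (int)std::floor(z * inv_dv);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
        escaped += w;
        break;
      }
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      double ma = mua[idx], ms = mus[idx];

      // distance to the nearest voxel face along the direction of travel
      double tb = BIG;
      if (ux > 0.0)      tb = std::min(tb, ((ix + 1) * dv - x) / ux);
      else if (ux < 0.0) tb = std::min(tb, (ix * dv - x) / ux);
      if (uy > 0.0)      tb = std::min(tb, ((iy + 1) * dv - y) / uy);
      else if (uy < 0.0) tb = std::min(tb, (iy * dv - y) / uy);
      if (uz > 0.0)      tb = std::min(tb, ((iz + 1) * dv - z) / uz);
      else if (uz < 0.0) tb = std::min(tb, (iz * dv - z) / uz);
      if (tb < 0.0) tb = 0.0;

      double s_scat = (ms > 0.0) ? tau / ms : BIG;
      bool scatter_here = (s_scat <= tb);
      double L = scatter_here ? s_scat : tb + NUDGE;

      if (ma > 0.0) {
        double frac = one_m_exp(ma * L);
        double dep = w * frac;
        track[idx] += dep / ma;  // integral of w over the sub-path
        absorbed += dep;
        w *= 1.0 - frac;
      } else {
        track[idx] += w * L;
      }

      x += ux * L; y += uy * L; z += uz * L;

      if (scatter_here) {
        double ct = hg_costheta(g, rng);
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double cp, sp;
        rand_azimuth(rng, cp, sp);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp;
          uy = st * sp;
          uz = (uz >= 0.0 ? ct : -ct);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          double nuz = -st * cp * den + uz * ct;
          double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
        }
        tau = -std::log(rng.u01());
      } else {
        tau -= ms * L;
        if (tau < 0.0) tau = 0.0;
      }

      if (w < roulette_threshold) {
        if (rng.u01() < roulette_survival) {
          gained += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          killed += w;
          break;
        }
      }
    }
  }

  return List::create(_["track_mm"] = track,
                      _["absorbed"] = absorbed,
                      _["escaped"] = escaped,
                      _["killed"] = killed,
                      _["gained"] = gained,
                      _["launched"] = (double)n_photons);
}
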