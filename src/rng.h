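#pragma once
#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding. Self-contained so that runs are
// bit-reproducible for a given seed independent of R's RNG state and of the
// platform's rand() implementation.
struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
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
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]: never 0, so -log(u) stays finite
  inline double runif() {
    return ((next() >> 11) + 1) * 1.1102230246251565e-16; // * 2^-53
  }
};

// Unpolarized Fresnel reflectance for |cos(theta_i)| = ci at an n1 -> n2
// interface; ct receives |cos(theta_t)|. Returns 1 under total internal
// reflection.
inline double fresnel_reflectance(double n1, double n2, double ci, double &ct) {
  if (ci > 1.0) ci = 1.0;
  if (n1 == n2) {
    ct = ci;
    return 0.0;
  }
  const double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  const double st = n1 / n2 * si;
  if (st >= 1.0) {
    ct = 0.0;
    return 1.0;
  }
  ct = std::sqrt(1.0 - st * st);
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine.
inline double sample_hg(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  const double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate the unit direction (ux,uy,uz) by deflection cosine ct and azimuth phi.
inline void spin_direction(double &ux, double &uy, double &uz, double ct,
                           double phi) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    const double nz = -st * cp * den + uz * ct;
    ux = nx;
    uy = ny;
    uz = nz;
  }
  // guard against slow drift from unit length
  const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm;
  uy /= norm;
  uz /= norm;
}
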