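#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;

// Photon-packet Monte Carlo for a laterally infinite tissue slab, optionally
// sandwiched between two clear glass slides, illuminated at normal incidence.
// Geometry along z (mm), z = 0 at the illuminated face of the stack.
//
// Conventions follow the multi-layer packet-weight scheme used by MCML-type
// codes: implicit absorption weighting (w *= mus/mut at each collision),
// Henyey-Greenstein scattering, Fresnel reflection/refraction at every
// refractive-index step, Russian roulette below a weight threshold. The
// specular reflection of the incident beam at the clear entry interfaces is
// computed analytically and excluded from the diffuse reflectance tally.

struct Layer {
  double z0, z1;  // top and bottom coordinate (mm)
  double n, mua, mus, g;
};

// Incoherent combination of two specular interface reflectances (multiple
// internal reflections between two parallel clear interfaces).
static inline double combine_specular(double r1, double r2) {
  return r1 + (1.0 - r1) * (1.0 - r1) * r2 / (1.0 - r1 * r2);
}

// [[Rcpp::export]]
List slab_mc_cpp(double mua, double mus, double g, double n_tissue,
                 double thickness, bool glass, double n_glass,
                 double glass_thickness, double n_ambient, double n_packets,
                 double seed, double roulette_threshold = 1e-4,
                 double roulette_survival = 0.1) {
  if (mua < 0 || mus < 0 || thickness <= 0 || n_tissue < 1 || n_ambient < 1 ||
      g <= -1 || g >= 1 + 1e-12)
    stop("non-physical slab properties");
  const long long N = (long long)n_packets;
  if (N < 1) stop("n_packets must be positive");

  std::vector<Layer> layers;
  if (glass) {
    layers.push_back({0.0, glass_thickness, n_glass, 0.0, 0.0, 0.0});
    layers.push_back(
        {glass_thickness, glass_thickness + thickness, n_tissue, mua, mus, g});
    layers.push_back({glass_thickness + thickness,
                      2 * glass_thickness + thickness, n_glass, 0.0, 0.0, 0.0});
  } else {
    layers.push_back({0.0, thickness, n_tissue, mua, mus, g});
  }
  const int L = (int)layers.size(), tissue_idx = glass ? 1 : 0;

  // analytic specular reflection of the collimated beam at the clear
  // interfaces crossed before the first scattering layer
  double ct;
  double rsp;
  if (glass) {
    const double r1 = fresnel_reflectance(n_ambient, n_glass, 1.0, ct);
    const double r2 = fresnel_reflectance(n_glass, n_tissue, 1.0, ct);
    rsp = combine_specular(r1, r2);
  } else {
    rsp = fresnel_reflectance(n_ambient, n_tissue, 1.0, ct);
  }

  Xoshiro rng((uint64_t)seed);
  const double mut = mua + mus;

  double sum_rd = 0, sum_tt = 0, sum_abs = 0, roulette_net = 0, lost = 0;
  double ss_rd = 0, ss_tt = 0;

  for (long long ip = 0; ip < N; ++ip) {
    double z = layers[tissue_idx].z0;
    double ux = 0, uy = 0, uz = 1;
    double w = 1.0 - rsp;
    int il = tissue_idx;
    double rd_i = 0, tt_i = 0;
    bool alive = true;

    while (alive) {
      const Layer &lay = layers[il];
      const double lmut = lay.mua + lay.mus;
      double s_geom;  // geometric path to travel before any event (mm)
      bool collide = false;
      double db = (uz > 0) ? (lay.z1 - z) / uz
                           : (uz < 0 ? (lay.z0 - z) / uz : R_PosInf);
      if (lmut > 0) {
        const double s = -std::log(rng.runif()) / lmut;
        if (s < db) {
          s_geom = s;
          collide = true;
        } else {
          s_geom = db;
        }
      } else {
        if (!R_FINITE(db)) {  // direction parallel to a clear layer
          lost += w;
          break;
        }
        s_geom = db;
      }

      z += uz * s_geom;

      if (collide) {
        sum_abs += w * lay.mua / lmut;
        w *= lay.mus / lmut;
        const double cth = sample_hg(lay.g, rng.runif());
        spin_direction(ux, uy, uz, cth, 2.0 * M_PI * rng.runif());
        if (w < roulette_threshold) {
          if (rng.runif() < roulette_survival) {
            roulette_net -= w * (1.0 / roulette_survival - 1.0);
            w /= roulette_survival;
          } else {
            roulette_net += w;
            alive = false;
          }
        }
        continue;
      }

      // at a layer boundary
      const bool down = uz > 0;
      const int inext = il + (down ? 1 : -1);
      const double n1 = lay.n;
      const double n2 =
          (inext < 0 || inext >= L) ? n_ambient : layers[inext].n;
      const double ci = std::fabs(uz);
      double ctr;
      const double R = fresnel_reflectance(n1, n2, ci, ctr);
      if (rng.runif() < R) {
        uz = -uz;  // internal reflection, stay in layer
        z = down ? lay.z1 : lay.z0;
      } else {
        const double scale = n1 / n2;
        ux *= scale;
        uy *= scale;
        uz = down ? ctr : -ctr;
        const double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm;
        uy /= norm;
        uz /= norm;
        if (inext < 0) {
          rd_i = w;
          alive = false;
        } else if (inext >= L) {
          tt_i = w;
          alive = false;
        } else {
          il = inext;
          z = down ? layers[inext].z0 : layers[inext].z1;
        }
      }
    }

    sum_rd += rd_i;
    sum_tt += tt_i;
    ss_rd += rd_i * rd_i;
    ss_tt += tt_i * tt_i;
  }

  const double Nd = (double)N;
  const double rd = sum_rd / Nd, tt = sum_tt / Nd;
  const double se_rd =
      std::sqrt(std::max(0.0, ss_rd / Nd - rd * rd) / Nd);
  const double se_tt =
      std::sqrt(std::max(0.0, ss_tt / Nd - tt * tt) / Nd);

  return List::create(
      _["Rd"] = rd, _["Tt"] = tt, _["absorbed"] = sum_abs / Nd,
      _["specular"] = rsp, _["roulette_net"] = roulette_net / Nd,
      _["lost"] = lost / Nd, _["se_Rd"] = se_rd, _["se_Tt"] = se_tt,
      _["n_packets"] = Nd);
}
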