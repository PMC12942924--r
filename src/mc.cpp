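// Voxel Monte Carlo photon transport for axisymmetric layered/nested media.
//
// Photons propagate in full 3D Cartesian space; the medium and the scoring
// grid are axisymmetric, described by annular (r, z) voxels. Free paths are
// sampled in optical depth and marched voxel-by-voxel with exact
// ray/cylinder-shell and ray/plane intersections, so heterogeneous media are
// handled without step bias. Fluence is scored with the track-length
// estimator; absorption uses implicit capture (weight *= albedo at each
// collision) with Russian roulette below a weight threshold. The top surface
// applies Fresnel reflection/transmission from the local refractive index
// ratio; lateral and bottom faces are absorbing (matte black).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: bit-reproducible across platforms
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1]
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

struct Photon {
  double x, y, z, ux, uy, uz, w;
};

inline void spin(Photon& p, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  if (std::fabs(uz) > 0.99999) {
    p.ux = st * cp;
    p.uy = st * sp;
    p.uz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    p.ux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    p.uy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    p.uz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
  p.ux /= nrm; p.uy /= nrm; p.uz /= nrm;
}

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 1.0 - 2.0 * u;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - t * t) / (2.0 * g);
}

// unpolarized Fresnel reflectance, internal incidence, index ratio n (>1)
inline double fresnel_R(double n, double ci) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n * si;          // Snell: n_in sin(i) = n_out sin(t), n = n_in/n_out
  if (st >= 1.0) return 1.0;   // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n * ci - ct) / (n * ci + ct);
  double rp = (n * ct - ci) / (n * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export]]
List mc_run_cpp(int nrv, int nzv, double dr, double dz,
                IntegerVector region,           // nrv*nzv, 0-based region ids
                NumericVector mua, NumericVector mus,
                NumericVector gg, NumericVector nn,
                int beam_kind,                  // 0 flat, 1 gaussian
                double beam_p1,                 // radius | waist w
                double beam_power,              // total power, W
                double n_photons, int nbatch,
                double seed,
                double w_threshold, double w_survive,
                double specular) {
  const double rmax = nrv * dr, zmax = nzv * dz;
  const double EPS = 1e-12 * std::max(rmax, zmax) + 1e-15;
  NumericVector flu(nrv * nzv * nbatch);        // track-length tallies
  NumericVector absorbed(nbatch), escaped(nbatch), roulette_net(nbatch),
                launched(nbatch);
  Rng rng((uint64_t)seed);

  const long long ntot = (long long)n_photons;
  for (int b = 0; b < nbatch; ++b) {
    long long nb = ntot / nbatch + (b < ntot % nbatch ? 1 : 0);
    double* fb = REAL(flu) + (size_t)b * nrv * nzv;
    for (long long ip = 0; ip < nb; ++ip) {
      Photon p;
      // launch at the top surface, direction -z
      double r;
      if (beam_kind == 0) {
        r = beam_p1 * std::sqrt(rng.unif());
        p.x = r; p.y = 0.0;
      } else {
        double sg = beam_p1 / 2.0;              // exp(-2r^2/w^2) = N(0, w/2) in 2D
        double u1 = rng.unif(), u2 = rng.unif();
        double rad = sg * std::sqrt(-2.0 * std::log(u1));
        p.x = rad * std::cos(2.0 * M_PI * u2);
        p.y = rad * std::sin(2.0 * M_PI * u2);
        r = rad;
      }
      p.z = zmax - EPS;
      p.ux = 0.0; p.uy = 0.0; p.uz = -1.0;
      p.w = specular;
      launched[b] += 1.0;                        // unit launch weight
      if (1.0 - specular > 0) escaped[b] += 1.0 - specular;
      if (r >= rmax) { escaped[b] += p.w; continue; }

      double tau = -std::log(rng.unif());
      bool alive = true;
      long long guard = 0;
      while (alive) {
        if (++guard > 100000000LL) { escaped[b] += p.w; break; }
        double rr = std::sqrt(p.x * p.x + p.y * p.y);
        int ir = (int)(rr / dr); if (ir >= nrv) ir = nrv - 1;
        int iz = (int)(p.z / dz);
        if (iz < 0) iz = 0; if (iz >= nzv) iz = nzv - 1;
        int reg = region[ir + nrv * (size_t)iz];
        double ma = mua[reg], ms = mus[reg], mt = ma + ms;

        // distance to voxel boundary (z planes and cylinder shells)
        double tb = R_PosInf;
        if (p.uz > 0) tb = ((iz + 1) * dz - p.z) / p.uz;
        else if (p.uz < 0) tb = (iz * dz - p.z) / p.uz;
        double a = p.ux * p.ux + p.uy * p.uy;
        if (a > 0) {
          double bq = p.x * p.ux + p.y * p.uy;       // b/2
          double Rout = (ir + 1) * dr;
          double cq = p.x * p.x + p.y * p.y - Rout * Rout;
          double disc = bq * bq - a * cq;            // cq <= 0 inside
          if (disc > 0) {
            double t_out = (-bq + std::sqrt(disc)) / a;
            if (t_out > 0 && t_out < tb) tb = t_out;
          }
          if (ir > 0 && bq < 0) {
            double Rin = ir * dr;
            double ci2 = p.x * p.x + p.y * p.y - Rin * Rin;
            double d2 = bq * bq - a * ci2;
            if (d2 > 0) {
              double t_in = (-bq - std::sqrt(d2)) / a;
              if (t_in > 0 && t_in < tb) tb = t_in;
            }
          }
        }
        if (tb < 0) tb = 0;

        double s_int = (mt > 0) ? tau / mt : R_PosInf;
        if (s_int <= tb) {
          // collision inside this voxel
          fb[ir + nrv * (size_t)iz] += p.w * s_int;
          p.x += s_int * p.ux; p.y += s_int * p.uy; p.z += s_int * p.uz;
          double dw = p.w * ma / mt;
          absorbed[b] += dw;
          p.w -= dw;
          if (ms <= 0) { alive = false; break; }   // pure absorber: weight 0
          double ct = hg_cos(gg[reg], rng.unif());
          spin(p, ct, 2.0 * M_PI * rng.unif());
          tau = -std::log(rng.unif());
          if (p.w < w_threshold) {
            if (rng.unif() < w_survive) {
              roulette_net[b] -= p.w * (1.0 / w_survive - 1.0);
              p.w /= w_survive;
            } else {
              roulette_net[b] += p.w;
              alive = false;
            }
          }
        } else {
          // traverse to the voxel boundary
          fb[ir + nrv * (size_t)iz] += p.w * tb;
          double step = tb + EPS;
          p.x += step * p.ux; p.y += step * p.uy; p.z += step * p.uz;
          if (mt > 0) tau -= mt * tb;
          if (tau < 0) tau = 0;
          // domain exits
          double r2 = p.x * p.x + p.y * p.y;
          if (r2 >= rmax * rmax || p.z <= 0.0) {   // matte lateral/bottom
            escaped[b] += p.w; alive = false; break;
          }
          if (p.z >= zmax) {                        // air interface: Fresnel
            double ci = p.uz;                       // cos of incidence
            double nrel = nn[reg];
            double R = (nrel == 1.0) ? 0.0 : fresnel_R(nrel, ci);
            if (rng.unif() < R) {
              p.uz = -p.uz;
              p.z = zmax - EPS;
            } else {
              escaped[b] += p.w; alive = false; break;
            }
          }
        }
      }
    }
  }
  // scale tallies to fluence: P * sum(w l) / (N_batch * V_voxel)
  NumericVector out(flu.size());
  for (int b = 0; b < nbatch; ++b) {
    long long nb = ntot / nbatch + (b < ntot % nbatch ? 1 : 0);
    for (int iz = 0; iz < nzv; ++iz) {
      for (int ir = 0; ir < nrv; ++ir) {
        double V = M_PI * ((ir + 1.0) * (ir + 1.0) - (double)ir * ir) *
                   dr * dr * dz;
        size_t k = ir + nrv * ((size_t)iz + (size_t)nzv * b);
        out[k] = beam_power * flu[k] / ((double)nb * V);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nrv, nzv, nbatch);
  return List::create(_["fluence"] = out, _["launched"] = launched,
                      _["absorbed"] = absorbed, _["escaped"] = escaped,
                      _["roulette_net"] = roulette_net);
}
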