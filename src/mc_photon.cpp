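// Weighted-photon Monte-Carlo transport on a labelled voxel grid.
//
// Exponential free paths with mu_t = mu_a + mu_s consumed voxel-by-voxel
// (DDA traversal), deposition of w * mu_a / mu_t at each interaction site,
// Henyey-Greenstein deflection, Russian roulette below a weight threshold.
// Launch model: focused Gaussian beam - waist position and propagation
// slope sampled independently, which reproduces the Gaussian-beam caustic
// w(z)^2 = w0^2 + (theta z)^2.
//
// Units: lengths in um, optical coefficients in 1/um. Deterministic given
// (seed, photon index): each photon owns an independent counter-seeded RNG.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- splitmix64 / xoshiro256++ ---------------------------------------------
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (stream * 0xD2B74407B1CE6E93ULL + 0x8C6E1D29ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    have_normal = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {              // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_normal; double cached_normal;
  inline double normal() {
    if (have_normal) { have_normal = false; return cached_normal; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    cached_normal = r * std::sin(a); have_normal = true;
    return r * std::cos(a);
  }
};

static inline double hg_cost(double g, double xi) {
  if (std::fabs(g) < 1e-6) return 2.0 * xi - 1.0;
  const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate unit vector (ux,uy,uz) by polar angle acos(cost), azimuth phi
static inline void scatter_dir(double &ux, double &uy, double &uz,
                               double cost, double phi) {
  const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  const double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp; uy = sint * sinp; uz = cost * (uz > 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    const double ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    const double nz = -sint * cosp * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// [[Rcpp::export(name = ".mc_trace")]]
List mc_trace_cpp(IntegerVector label, IntegerVector dims, double pitch,
                  NumericMatrix props, double n_photons_d, double seed_d,
                  NumericVector beam, double roulette_threshold,
                  double roulette_survival) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  if ((size_t)label.size() != N) stop("label grid does not match dims");
  const int nmat = props.nrow();
  const uint64_t n_photons = (uint64_t)n_photons_d;
  const uint64_t master = (uint64_t)seed_d;
  // beam: fx fy fz sigma_pos sigma_ang  (focal-cone Gaussian launch)
  const double fx = beam[0], fy = beam[1], fz = beam[2];
  const double sig_p = beam[3], sig_a = beam[4];
  const bool roulette = roulette_threshold > 0.0;
  if (roulette && (roulette_survival <= 0.0 || roulette_survival >= 1.0))
    stop("roulette survival probability must be in (0, 1)");

  std::vector<double> mua(nmat), mus(nmat), mut(nmat), gg(nmat);
  for (int m = 0; m < nmat; ++m) {
    mua[m] = props(m, 0); mus[m] = props(m, 1); gg[m] = props(m, 2);
    if (mua[m] < 0 || mus[m] < 0) stop("negative optical coefficient");
    if (gg[m] < -1 || gg[m] > 1) stop("anisotropy outside [-1, 1]");
    mut[m] = mua[m] + mus[m];
  }

  NumericVector absorbed(N);           // deposited weight per voxel
  const double Lx = nx * pitch, Ly = ny * pitch, Lz = nz * pitch;
  double tot_abs = 0.0, tot_esc = 0.0;
  const double eps = 1e-7 * pitch;
  double tot_lost = 0.0;                // guard-terminated weight (diagnostic)
  Rng rng;

  for (uint64_t ph = 0; ph < n_photons; ++ph) {
    rng.seed(master, ph);
    // launch: aim through a waist-sampled point at the focus
    double dirx, diry, dirz, x, y, z;
    if (sig_a > 0.0 || sig_p > 0.0) {
      const double xw = fx + sig_p * rng.normal();
      const double yw = fy + sig_p * rng.normal();
      const double sx = sig_a * rng.normal();
      const double sy = sig_a * rng.normal();
      const double nrm = std::sqrt(sx * sx + sy * sy + 1.0);
      dirx = sx / nrm; diry = sy / nrm; dirz = 1.0 / nrm;
      x = xw - (dirx / dirz) * fz;
      y = yw - (diry / dirz) * fz;
      z = eps;
    } else {                            // collimated pencil beam
      dirx = 0.0; diry = 0.0; dirz = 1.0;
      x = fx; y = fy; z = eps;
    }
    double w = 1.0;
    if (x <= 0 || x >= Lx || y <= 0 || y >= Ly) { tot_esc += w; continue; }

    double tau = -std::log(rng.unif());
    long guard = 0;
    while (true) {
      if (++guard > 2000000) { tot_lost += w; break; }  // defensive
      const int i = (int)std::floor(x / pitch);
      const int j = (int)std::floor(y / pitch);
      const int k = (int)std::floor(z / pitch);
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
        tot_esc += w; break;
      }
      const int m = label[(size_t)i + nx * ((size_t)j + (size_t)ny * k)];
      if (m < 0 || m >= nmat) stop("voxel label without property entry");
      // distance to the voxel boundary along the current direction
      double db = 1e30;
      if (dirx > 0) db = std::min(db, ((i + 1) * pitch - x) / dirx);
      else if (dirx < 0) db = std::min(db, (i * pitch - x) / dirx);
      if (diry > 0) db = std::min(db, ((j + 1) * pitch - y) / diry);
      else if (diry < 0) db = std::min(db, (j * pitch - y) / diry);
      if (dirz > 0) db = std::min(db, ((k + 1) * pitch - z) / dirz);
      else if (dirz < 0) db = std::min(db, (k * pitch - z) / dirz);
      db = std::max(db, 0.0) + eps;

      const double mt = mut[m];
      if (mt <= 0.0 || mt * db < tau) { // free flight through the voxel
        if (mt > 0.0) tau -= mt * db;
        x += dirx * db; y += diry * db; z += dirz * db;
        continue;
      }
      // interaction inside this voxel
      const double s = tau / mt;
      x += dirx * s; y += diry * s; z += dirz * s;
      const double dep = w * mua[m] / mt;
      absorbed[(size_t)i + nx * ((size_t)j + (size_t)ny * k)] += dep;
      tot_abs += dep;
      w -= dep;
      if (w <= 0.0) break;
      scatter_dir(dirx, diry, dirz, hg_cost(gg[m], rng.unif()),
                  2.0 * M_PI * rng.unif());
      tau = -std::log(rng.unif());
      if (roulette && w < roulette_threshold) {
        if (rng.unif() < roulette_survival) w /= roulette_survival;
        else break;                     // killed (unbiased on average)
      }
    }
  }

  absorbed.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["absorbed"] = absorbed,
                      _["launched"] = (double)n_photons,
                      _["absorbed_total"] = tot_abs,
                      _["escaped"] = tot_esc,
                      _["lost"] = tot_lost);
}

// [[Rcpp::export(name = ".mc_hg_sample")]]
NumericVector mc_hg_sample_cpp(int n, double g, double seed_d) {
  Rng rng; rng.seed((uint64_t)seed_d, 0x48474847ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cost(g, rng.unif());
  return out;
}

// [[Rcpp::export(name = ".mc_beam_sample")]]
NumericMatrix mc_beam_sample_cpp(int n, NumericVector beam, double z_plane,
                                 double seed_d) {
  Rng rng; rng.seed((uint64_t)seed_d, 0xBEA4BEA4ULL);
  const double fx = beam[0], fy = beam[1], fz = beam[2];
  const double sig_p = beam[3], sig_a = beam[4];
  NumericMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    const double xw = fx + sig_p * rng.normal();
    const double yw = fy + sig_p * rng.normal();
    const double sx = sig_a * rng.normal();
    const double sy = sig_a * rng.normal();
    const double nrm = std::sqrt(sx * sx + sy * sy + 1.0);
    const double dirx = sx / nrm, diry = sy / nrm, dirz = 1.0 / nrm;
    out(i, 0) = xw + (dirx / dirz) * (z_plane - fz);
    out(i, 1) = yw + (diry / dirz) * (z_plane - fz);
    out(i, 2) = dirx; out(i, 3) = diry; out(i, 4) = dirz;
  }
  return out;
}
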