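// 2D k-space pseudospectral time-domain solver for linear acoustics in a
// homogeneous medium with quadratic (y = 2) power-law absorption.
//
// First-order coupled pressure/velocity update on spatially staggered grids,
// exact spectral derivatives with the k-space temporal correction
// kappa = sinc(c k dt / 2), split-field PML, and a per-step spectral
// amplitude filter for the absorption law alpha(f) = alpha0 f^2 (the
// thermoviscous case, which carries no dispersion correction).
//
// Units: lengths in mm, time in us, frequencies in MHz, sound speed in mm/us,
// absorption in Np/mm at 1 MHz (converted from dB/(MHz^2 cm) on the R side).

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline double sinc(double x) {
  return (std::fabs(x) < 1e-12) ? 1.0 : std::sin(x) / x;
}

// [[Rcpp::export(name = ".ks_propagate")]]
List ks_propagate_cpp(NumericMatrix p0,
                      double dx, double dt, int nt,
                      double c0, double rho0, double alpha_np,
                      int pml_size, double pml_alpha,
                      NumericMatrix sensor_ij,
                      bool smooth_p0,
                      bool record_energy,
                      Nullable<NumericMatrix> ux0 = R_NilValue,
                      Nullable<NumericMatrix> uz0 = R_NilValue) {
  const int nx = p0.nrow(), nz = p0.ncol();
  const size_t N = (size_t)nx * nz;
  const int nxh = nx / 2 + 1;
  const size_t NC = (size_t)nz * nxh;
  const int ns = sensor_ij.nrow();
  if (nt < 1) stop("nt must be >= 1");
  if (2 * pml_size >= nx || 2 * pml_size >= nz)
    stop("PML occupies the whole grid");
  const double cfl = c0 * dt / dx;
  if (cfl > 0.3 + 1e-12)
    stop("CFL number %.3f exceeds the supported limit 0.3", cfl);

  // ---- FFT work buffers and plans (x varies fastest: row-major (nz, nx)) --
  double *rwork = fftw_alloc_real(N);
  fftw_complex *cw1 = fftw_alloc_complex(NC);
  fftw_complex *cw2 = fftw_alloc_complex(NC);
  fftw_plan pf = fftw_plan_dft_r2c_2d(nz, nx, rwork, cw1, FFTW_MEASURE);
  fftw_plan pb = fftw_plan_dft_c2r_2d(nz, nx, cw2, rwork, FFTW_MEASURE);

  // ---- wavenumbers --------------------------------------------------------
  std::vector<double> kx(nxh), kz(nz);
  for (int i = 0; i < nxh; ++i) kx[i] = 2.0 * M_PI * i / (nx * dx);
  for (int j = 0; j < nz; ++j) {
    int jj = (j <= nz / 2) ? j : j - nz;
    kz[j] = 2.0 * M_PI * jj / (nz * dx);
  }
  const double kx_max = M_PI / dx, kz_max = M_PI / dx;

  // ---- spectral multipliers ----------------------------------------------
  // MGx/MGz: gradient of p onto the staggered velocity points (shift +dx/2)
  // MDx/MDz: divergence of u back onto pressure points (shift -dx/2),
  //          including the attenuation filter and 1/N normalisation
  // WB:      attenuation write-back filter for the stored velocity fields
  const bool lossy = alpha_np > 0.0;
  std::vector<cplx> MGx(NC), MGz(NC), MDx(NC), MDz(NC);
  std::vector<double> WB(lossy ? NC : 0);
  const double invN = 1.0 / (double)N;
  for (int j = 0; j < nz; ++j) {
    for (int i = 0; i < nxh; ++i) {
      const size_t h = (size_t)j * nxh + i;
      const double k = std::hypot(kx[i], kz[j]);
      const double kap = sinc(0.5 * c0 * k * dt);
      const cplx ikx(0.0, kx[i] * kap), ikz(0.0, kz[j] * kap);
      const cplx shp_x = std::exp(cplx(0.0, 0.5 * kx[i] * dx));
      const cplx shp_z = std::exp(cplx(0.0, 0.5 * kz[j] * dx));
      MGx[h] = ikx * shp_x * invN;
      MGz[h] = ikz * shp_z * invN;
      double att2 = 1.0;
      if (lossy) {
        const double f = c0 * k / (2.0 * M_PI);      // MHz
        att2 = std::exp(-2.0 * alpha_np * f * f * c0 * dt);
        WB[h] = att2 * invN;
      }
      MDx[h] = ikx * std::conj(shp_x) * att2 * invN;
      MDz[h] = ikz * std::conj(shp_z) * att2 * invN;
    }
  }

  // ---- fields -------------------------------------------------------------
  std::vector<double> px(N), pz(N), ux(N, 0.0), uz(N, 0.0);
  std::vector<double> gx(N), gz(N), dxu(N), dzu(N);
  std::vector<double> uxp, uzp;              // previous u (energy diagnostic)
  if (record_energy) { uxp.assign(N, 0.0); uzp.assign(N, 0.0); }

  // optional source smoothing: radially symmetric Blackman window in
  // k-space; removes staircase/Gibbs ringing from cell-snapped initial
  // pressure and keeps a band-limited point source isotropic
  for (size_t q = 0; q < N; ++q) rwork[q] = p0[q];
  if (smooth_p0) {
    fftw_execute(pf);
    (void)kz_max;
    for (int j = 0; j < nz; ++j) {
      for (int i = 0; i < nxh; ++i) {
        const double r = std::hypot(kx[i], kz[j]) / kx_max;
        const double w = (r >= 1.0) ? 0.0
          : 0.42 + 0.5 * std::cos(M_PI * r) + 0.08 * std::cos(2.0 * M_PI * r);
        const size_t h = (size_t)j * nxh + i;
        cw2[h][0] = cw1[h][0] * w * invN;
        cw2[h][1] = cw1[h][1] * w * invN;
      }
    }
    fftw_execute(pb);
  }
  for (size_t q = 0; q < N; ++q) { px[q] = 0.5 * rwork[q]; pz[q] = px[q]; }

  bool have_u0 = false;
  if (ux0.isNotNull() && uz0.isNotNull()) {
    NumericMatrix u0x(ux0), u0z(uz0);
    if (u0x.nrow() != nx || u0x.ncol() != nz ||
        u0z.nrow() != nx || u0z.ncol() != nz)
      stop("velocity initial conditions must match the grid");
    for (size_t q = 0; q < N; ++q) { ux[q] = u0x[q]; uz[q] = u0z[q]; }
    have_u0 = true;
  }

  // ---- PML damping profiles (quartic grading, exp applied per half-step) --
  std::vector<double> ax(nx, 1.0), az(nz, 1.0);
  if (pml_size > 0) {
    const double s0 = pml_alpha * c0 / dx;
    for (int i = 0; i < nx; ++i) {
      double d = 0.0;
      if (i < pml_size) d = (double)(pml_size - i) / pml_size;
      else if (i >= nx - pml_size) d = (double)(i - (nx - pml_size - 1)) / pml_size;
      if (d > 0.0) ax[i] = std::exp(-s0 * std::pow(d, 4) * dt / 2.0);
    }
    for (int j = 0; j < nz; ++j) {
      double d = 0.0;
      if (j < pml_size) d = (double)(pml_size - j) / pml_size;
      else if (j >= nz - pml_size) d = (double)(j - (nz - pml_size - 1)) / pml_size;
      if (d > 0.0) az[j] = std::exp(-s0 * std::pow(d, 4) * dt / 2.0);
    }
  }

  // ---- sensor bilinear interpolation weights ------------------------------
  std::vector<int> s_i0(ns), s_j0(ns);
  std::vector<double> s_wx(ns), s_wz(ns);
  for (int s = 0; s < ns; ++s) {
    double fi = sensor_ij(s, 0), fj = sensor_ij(s, 1);
    if (fi < 0 || fi > nx - 1 || fj < 0 || fj > nz - 1)
      stop("sensor %d outside the grid", s + 1);
    int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > nz - 2) j0 = nz - 2;
    s_i0[s] = i0; s_j0[s] = j0;
    s_wx[s] = fi - i0; s_wz[s] = fj - j0;
  }

  NumericMatrix traces(nt, ns);
  NumericVector energy(record_energy ? nt : 0);
  const double dt_rho = dt / rho0;
  const double dt_rc2 = dt * rho0 * c0 * c0;

  for (int n = 0; n < nt; ++n) {
    // -- velocity update ----------------------------------------------------
    if (record_energy) { uxp = ux; uzp = uz; }
    if (!(n == 0 && have_u0)) {
      for (size_t q = 0; q < N; ++q) rwork[q] = px[q] + pz[q];
      fftw_execute(pf);                                    // P(k)
      for (size_t h = 0; h < NC; ++h) {
        const cplx v(cw1[h][0], cw1[h][1]);
        const cplx g = v * MGx[h];
        cw2[h][0] = g.real(); cw2[h][1] = g.imag();
      }
      fftw_execute(pb);
      std::copy(rwork, rwork + N, gx.begin());
      for (size_t h = 0; h < NC; ++h) {
        const cplx v(cw1[h][0], cw1[h][1]);
        const cplx g = v * MGz[h];
        cw2[h][0] = g.real(); cw2[h][1] = g.imag();
      }
      fftw_execute(pb);
      std::copy(rwork, rwork + N, gz.begin());
      // first velocity update covers only dt/2 (u is staggered in time)
      const double sv = (n == 0) ? 0.5 : 1.0;
      for (int j = 0; j < nz; ++j) {
        const size_t off = (size_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          const size_t q = off + i;
          ux[q] = ax[i] * (ax[i] * ux[q] - sv * dt_rho * gx[q]);
          uz[q] = az[j] * (az[j] * uz[q] - sv * dt_rho * gz[q]);
        }
      }
    }

    // -- energy diagnostic: p still holds p(t_n); the product of the
    //    velocities bracketing t_n gives a centred kinetic term ----------
    if (record_energy) {
      double e = 0.0;
      const int m = pml_size + 5;
      for (int j = m; j < nz - m; ++j) {
        const size_t off = (size_t)j * nx;
        for (int i = m; i < nx - m; ++i) {
          const size_t q = off + i;
          const double p = px[q] + pz[q];
          e += p * p / (2.0 * rho0 * c0 * c0) +
               0.5 * rho0 * (ux[q] * uxp[q] + uz[q] * uzp[q]);
        }
      }
      energy[n] = e;
    }

    // -- pressure update ----------------------------------------------------
    std::copy(ux.begin(), ux.end(), rwork);
    fftw_execute(pf);
    for (size_t h = 0; h < NC; ++h) {
      const cplx v(cw1[h][0], cw1[h][1]);
      const cplx g = v * MDx[h];
      cw2[h][0] = g.real(); cw2[h][1] = g.imag();
    }
    fftw_execute(pb);
    std::copy(rwork, rwork + N, dxu.begin());
    if (lossy) {                                   // attenuate stored ux
      for (size_t h = 0; h < NC; ++h) {
        cw2[h][0] = cw1[h][0] * WB[h]; cw2[h][1] = cw1[h][1] * WB[h];
      }
      fftw_execute(pb);
      std::copy(rwork, rwork + N, ux.begin());
    }

    std::copy(uz.begin(), uz.end(), rwork);
    fftw_execute(pf);
    for (size_t h = 0; h < NC; ++h) {
      const cplx v(cw1[h][0], cw1[h][1]);
      const cplx g = v * MDz[h];
      cw2[h][0] = g.real(); cw2[h][1] = g.imag();
    }
    fftw_execute(pb);
    std::copy(rwork, rwork + N, dzu.begin());
    if (lossy) {
      for (size_t h = 0; h < NC; ++h) {
        cw2[h][0] = cw1[h][0] * WB[h]; cw2[h][1] = cw1[h][1] * WB[h];
      }
      fftw_execute(pb);
      std::copy(rwork, rwork + N, uz.begin());
    }

    for (int j = 0; j < nz; ++j) {
      const size_t off = (size_t)j * nx;
      for (int i = 0; i < nx; ++i) {
        const size_t q = off + i;
        px[q] = ax[i] * (ax[i] * px[q] - dt_rc2 * dxu[q]);
        pz[q] = az[j] * (az[j] * pz[q] - dt_rc2 * dzu[q]);
      }
    }

    // -- record -------------------------------------------------------------
    for (int s = 0; s < ns; ++s) {
      const int i0 = s_i0[s], j0 = s_j0[s];
      const double wxs = s_wx[s], wzs = s_wz[s];
      const size_t q00 = (size_t)j0 * nx + i0;
      const double p00 = px[q00] + pz[q00];
      const double p10 = px[q00 + 1] + pz[q00 + 1];
      const double p01 = px[q00 + nx] + pz[q00 + nx];
      const double p11 = px[q00 + nx + 1] + pz[q00 + nx + 1];
      traces(n, s) = (1 - wxs) * (1 - wzs) * p00 + wxs * (1 - wzs) * p10 +
                     (1 - wxs) * wzs * p01 + wxs * wzs * p11;
    }
    if ((n & 127) == 0) {
      const size_t mid = N / 2;
      if (!std::isfinite(px[mid] + pz[mid]))
        stop("numerical blow-up detected at step %d", n + 1);
    }
  }

  NumericMatrix p_final(nx, nz);
  for (size_t q = 0; q < N; ++q) p_final[q] = px[q] + pz[q];

  fftw_destroy_plan(pf);
  fftw_destroy_plan(pb);
  fftw_free(rwork); fftw_free(cw1); fftw_free(cw2);

  List out = List::create(_["traces"] = traces, _["p_final"] = p_final);
  if (record_energy) out["energy"] = energy;
  return out;
}
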