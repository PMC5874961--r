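#include <Rcpp.h>
#include <vector>
#include "curve.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector curve_cum_cpp(NumericVector depth, NumericVector dose,
                            NumericVector cum, NumericVector w) {
  PwlCurve c{depth.begin(), dose.begin(), cum.begin(), (int)depth.size()};
  NumericVector out(w.size());
  for (R_xlen_t i = 0; i < w.size(); ++i) out[i] = c.cum(w[i]);
  return out;
}

// cumulative curve integral with a forward-moving segment cursor: valid for
// monotonically non-decreasing w within one proton track
static inline double cum_at(const double *d, const double *y, const double *C,
                            int n, int &lo, double w) {
  if (w <= d[0]) return 0.0;
  if (w >= d[n - 1]) return C[n - 1];
  while (lo + 1 < n - 1 && d[lo + 1] <= w) ++lo;
  double t = w - d[lo];
  double slope = (y[lo + 1] - y[lo]) / (d[lo + 1] - d[lo]);
  return C[lo] + t * (y[lo] + 0.5 * slope * t);
}

// Box-Muller pair over R's uniform stream: two standard normals per call.
// Deterministic for a given R seed (the kick sampler of the engine).
static inline void norm_pair(double &n1, double &n2) {
  double u1 = unif_rand(), u2 = unif_rand();
  while (u1 <= 0.0) u1 = unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1));
  double a = 2.0 * M_PI * u2;
  n1 = r * std::cos(a);
  n2 = r * std::sin(a);
}

// Simplified Monte Carlo transport: one-voxel z-steps, midpoint-voxel
// scoring, Highland kicks telescoped in quadrature, termination at the
// curve's nominal range or lateral escape. Internally rsp and dose are
// interleaved per voxel in a z-fastest scratch buffer so each step touches
// one cache line; input and output stay in R's natural x-fastest layout.
// [[Rcpp::export]]
NumericVector transport_cpp(NumericVector rsp, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericVector x0, NumericVector y0,
                            NumericVector z0, NumericVector tx0,
                            NumericVector ty0, NumericVector cdepth,
                            NumericVector cdose, NumericVector ccum,
                            double nominal_range, double alpha, double p,
                            double rest_energy, double highland_k,
                            double X0_water, bool log_correction,
                            double rs_wet_mm, double max_kick_sigma,
                            double max_angle) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  // voxel (0,0,0) spans [xe0, xe0 + dx) etc.
  const double xe0 = origin[0] - dx / 2.0;
  const double ye0 = origin[1] - dy / 2.0;
  const double ze0 = origin[2] - dz / 2.0;
  const double inv_p = 1.0 / p;
  const R_xlen_t nprot = x0.size();
  const double *cd = cdepth.begin(), *cy = cdose.begin(), *cc = ccum.begin();
  const int cn = (int)cdepth.size();
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;

  // interleaved (rsp, dose) pairs, z-fastest
  std::vector<double> buf(2 * nvox);
  {
    const double *g = rsp.begin();
    for (int k = 0; k < nz; ++k)
      for (int iy = 0; iy < ny; ++iy) {
        const double *row = g + (R_xlen_t)nx * (iy + (R_xlen_t)ny * k);
        R_xlen_t base = (R_xlen_t)k * 2 +
                        2 * (R_xlen_t)nz * (R_xlen_t)nx * iy;
        for (int ix = 0; ix < nx; ++ix) {
          buf[base + 2 * (R_xlen_t)nz * ix] = row[ix];
          buf[base + 2 * (R_xlen_t)nz * ix + 1] = 0.0;
        }
      }
  }

  RNGScope scope;
  for (R_xlen_t ip = 0; ip < nprot; ++ip) {
    double x = x0[ip], y = y0[ip], tx = tx0[ip], ty = ty0[ip];
    double w = rs_wet_mm;
    int cur = 0;                // curve segment cursor (w is non-decreasing)
    double cum_w = cum_at(cd, cy, cc, cn, cur, w);
    // ballistic drift from the proton's plane to the grid entrance face
    double zdrift = ze0 - z0[ip];
    if (zdrift > 0) { x += tx * zdrift; y += ty * zdrift; }
    for (int k = 0; k < nz; ++k) {
      double r = nominal_range - w;
      if (r <= 0) break;
      // midpoint of this z-step
      double mx = x + tx * dz / 2.0;
      double my = y + ty * dz / 2.0;
      int ix = (int)std::floor((mx - xe0) / dx);
      int iy = (int)std::floor((my - ye0) / dy);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break; // lateral escape
      R_xlen_t idx =
          2 * ((R_xlen_t)k + (R_xlen_t)nz * (ix + (R_xlen_t)nx * iy));
      double pf = std::sqrt(1.0 + tx * tx + ty * ty);
      double dw = dz * buf[idx] * pf;
      // advance with the pre-kick direction, then scatter
      x += tx * dz;
      y += ty * dz;
      if (dw > 0) {
        double cum_w2 = cum_at(cd, cy, cc, cn, cur, w + dw);
        buf[idx + 1] += cum_w2 - cum_w;
        // Highland kick: difference-in-quadrature of the cumulative angle,
        // pv evaluated at the current residual range
        double E = std::pow(r / alpha, inv_p);
        double pv = E * (E + 2.0 * rest_energy) / (E + rest_energy);
        double s2 = highland_theta0_sq(w + dw, pv, highland_k, X0_water,
                                       log_correction) -
                    highland_theta0_sq(w, pv, highland_k, X0_water,
                                       log_correction);
        double s = s2 > 0 ? std::sqrt(s2) : 0.0;
        if (s > max_kick_sigma) s = max_kick_sigma;
        if (s > 0) {
          double n1, n2;
          norm_pair(n1, n2);
          tx += n1 * s;
          ty += n2 * s;
          if (tx > max_angle) tx = max_angle;
          if (tx < -max_angle) tx = -max_angle;
          if (ty > max_angle) ty = max_angle;
          if (ty < -max_angle) ty = -max_angle;
        }
        cum_w = cum_w2;
      }
      w += dw;
    }
  }

  NumericVector dose(nvox);
  {
    double *D = dose.begin();
    for (int k = 0; k < nz; ++k)
      for (int iy = 0; iy < ny; ++iy) {
        double *row = D + (R_xlen_t)nx * (iy + (R_xlen_t)ny * k);
        R_xlen_t base = (R_xlen_t)k * 2 +
                        2 * (R_xlen_t)nz * (R_xlen_t)nx * iy + 1;
        for (int ix = 0; ix < nx; ++ix)
          row[ix] = buf[base + 2 * (R_xlen_t)nz * ix];
      }
  }
  return dose;
}
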