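#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Offset {
  double ox, oy, oz, dist2;
};

static inline bool trilinear(const double *v, const int *n, const double *sp,
                             const double *orig, double px, double py,
                             double pz, double &out) {
  // sample positions are in mm; voxel centers at orig + i*sp
  double fx = (px - orig[0]) / sp[0];
  double fy = (py - orig[1]) / sp[1];
  double fz = (pz - orig[2]) / sp[2];
  // only sample inside the voxel-center bounding box
  if (fx < 0 || fx > n[0] - 1 || fy < 0 || fy > n[1] - 1 || fz < 0 ||
      fz > n[2] - 1)
    return false;
  int ix = std::min((int)std::floor(fx), n[0] - 2);
  int iy = std::min((int)std::floor(fy), n[1] - 2);
  int iz = std::min((int)std::floor(fz), n[2] - 2);
  if (n[0] < 2 || n[1] < 2 || n[2] < 2) return false;
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  auto at = [&](int a, int b, int c) {
    return v[a + (R_xlen_t)n[0] * (b + (R_xlen_t)n[1] * c)];
  };
  double c00 = at(ix, iy, iz) * (1 - wx) + at(ix + 1, iy, iz) * wx;
  double c10 = at(ix, iy + 1, iz) * (1 - wx) + at(ix + 1, iy + 1, iz) * wx;
  double c01 = at(ix, iy, iz + 1) * (1 - wx) + at(ix + 1, iy, iz + 1) * wx;
  double c11 =
      at(ix, iy + 1, iz + 1) * (1 - wx) + at(ix + 1, iy + 1, iz + 1) * wx;
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  out = c0 * (1 - wz) + c1 * wz;
  return true;
}

// Global-normalization gamma index with exhaustive discrete search over a
// +/- search_mm window at sub_mm sampling of the trilinearly interpolated
// reference. Returns per-voxel gamma; NA_REAL below the cutoff.
// [[Rcpp::export]]
NumericVector gamma_cpp(NumericVector reference, NumericVector evaluated,
                        IntegerVector dims, NumericVector spacing,
                        NumericVector origin, double dta_mm, double dd_abs,
                        double cutoff_abs, double search_mm, double sub_mm) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double orig[3] = {origin[0], origin[1], origin[2]};
  const double *ref = reference.begin();
  const double *ev = evaluated.begin();

  // offsets sorted by distance for early termination
  std::vector<Offset> offs;
  int mx = (int)std::floor(search_mm / sub_mm);
  offs.reserve((2 * mx + 1) * (2 * mx + 1) * (2 * mx + 1));
  for (int a = -mx; a <= mx; ++a)
    for (int b = -mx; b <= mx; ++b)
      for (int c = -mx; c <= mx; ++c) {
        double ox = a * sub_mm, oy = b * sub_mm, oz = c * sub_mm;
        offs.push_back({ox, oy, oz, ox * ox + oy * oy + oz * oz});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &l, const Offset &r) { return l.dist2 < r.dist2; });

  NumericVector gamma(reference.size());
  const double dta2 = dta_mm * dta_mm, dd2 = dd_abs * dd_abs;
  R_xlen_t i = 0;
  for (int c = 0; c < n[2]; ++c)
    for (int b = 0; b < n[1]; ++b)
      for (int a = 0; a < n[0]; ++a, ++i) {
        if (ref[i] < cutoff_abs) {
          gamma[i] = NA_REAL;
          continue;
        }
        double px = orig[0] + a * sp[0];
        double py = orig[1] + b * sp[1];
        double pz = orig[2] + c * sp[2];
        double de = ev[i];
        double best = R_PosInf;
        for (const Offset &o : offs) {
          double geo = o.dist2 / dta2;
          if (geo >= best) break; // sorted: nothing closer remains
          double dr;
          if (!trilinear(ref, n, sp, orig, px + o.ox, py + o.oy, pz + o.oz,
                         dr))
            continue;
          double diff = de - dr;
          double g2 = geo + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
        gamma[i] = std::sqrt(best);
      }
  return gamma;
}
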