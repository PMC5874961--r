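#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Exact incremental voxel walk (Amanatides-Woo) accumulating
// chord-length * rsp over the voxels a segment traverses. Voxel intervals
// are half-open [lo, hi); segment portions outside the grid contribute 0.
// [[Rcpp::export]]
double wet_segment_cpp(NumericVector rsp, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       NumericVector p0, NumericVector p1) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  double e0[3], u[3];
  double L = 0.0;
  for (int a = 0; a < 3; ++a) {
    e0[a] = origin[a] - spacing[a] / 2.0;
    u[a] = p1[a] - p0[a];
    L += u[a] * u[a];
  }
  L = std::sqrt(L);
  if (L == 0.0) return 0.0;
  for (int a = 0; a < 3; ++a) u[a] /= L;

  int iv[3], step[3];
  double tmax[3], tdelta[3];
  for (int a = 0; a < 3; ++a) {
    iv[a] = (int)std::floor((p0[a] - e0[a]) / spacing[a]);
    if (u[a] > 0) {
      step[a] = 1;
      tmax[a] = (e0[a] + (iv[a] + 1) * spacing[a] - p0[a]) / u[a];
      tdelta[a] = spacing[a] / u[a];
    } else if (u[a] < 0) {
      step[a] = -1;
      tmax[a] = (e0[a] + iv[a] * spacing[a] - p0[a]) / u[a];
      tdelta[a] = -spacing[a] / u[a];
    } else {
      step[a] = 0;
      tmax[a] = R_PosInf;
      tdelta[a] = R_PosInf;
    }
  }

  const double *g = rsp.begin();
  double t = 0.0, wet = 0.0;
  while (t < L) {
    int a = 0;
    if (tmax[1] < tmax[a]) a = 1;
    if (tmax[2] < tmax[a]) a = 2;
    double tnext = std::min(tmax[a], L);
    double seg = tnext - t;
    if (seg > 0 && iv[0] >= 0 && iv[0] < n[0] && iv[1] >= 0 && iv[1] < n[1] &&
        iv[2] >= 0 && iv[2] < n[2]) {
      R_xlen_t idx = iv[0] + (R_xlen_t)n[0] * (iv[1] + (R_xlen_t)n[1] * iv[2]);
      wet += seg * g[idx];
    }
    if (tmax[a] >= L) break;
    t = tmax[a];
    iv[a] += step[a];
    tmax[a] += tdelta[a];
    // once past the far side along the travel direction the ray cannot
    // re-enter the grid on that axis
    if ((step[a] > 0 && iv[a] >= n[a]) || (step[a] < 0 && iv[a] < 0)) break;
  }
  return wet;
}
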