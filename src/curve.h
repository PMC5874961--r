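#ifndef SMCPROTON_CURVE_H
#define SMCPROTON_CURVE_H

#include <cmath>

// Exact cumulative integral of a piecewise-linear curve tabulated at
// (d[i], y[i]) with node cumulative values C[i] (trapezoid partial sums).
// Below d[0] the integral is 0; above d[n-1] it is constant.
struct PwlCurve {
  const double *d, *y, *C;
  int n;
  double cum(double w) const {
    if (w <= d[0]) return 0.0;
    if (w >= d[n - 1]) return C[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (d[mid] <= w) lo = mid; else hi = mid;
    }
    double t = w - d[lo];
    double slope = (y[lo + 1] - y[lo]) / (d[lo + 1] - d[lo]);
    return C[lo] + t * (y[lo] + 0.5 * slope * t);
  }
};

// Squared cumulative Highland angle after w mm of water for kinematic
// factor pv (MeV); log-correction factor floored at 0.
inline double highland_theta0_sq(double w, double pv, double k, double X0,
                                 bool logc) {
  if (w <= 0.0 || pv <= 0.0) return 0.0;
  double f = 1.0;
  if (logc) {
    f = 1.0 + std::log10(w / X0) / 9.0;
    if (f < 0.0) f = 0.0;
  }
  double t = (k / pv) * std::sqrt(w / X0) * f;
  return t * t;
}

#endif
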