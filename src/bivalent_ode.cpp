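#include <Rcpp.h>
#include <cmath>
#include <vector>

// Bivalent-analyte surface kinetics.
//
// One analyte molecule engages up to two immobilized ligand sites:
//   AL  (response R1): singly bound,  AL2 (response R2): doubly bound.
//   free sites = rmax - R1 - 2*R2
//   dR1/dt = 2*ka1*C*free - kd1*R1 - ka2*R1*free + 2*kd2*R2
//   dR2/dt = ka2*R1*free - 2*kd2*R2
// signal = R1 + R2. ka2 has units RU^-1 s^-1 (surface-species reaction).
//
// Integrated with an adaptive Dormand-Prince 5(4) pair; steps are clipped to
// each requested output time so trajectories are exact at grid points.

namespace {

struct BivParams {
  double ka1, kd1, ka2, kd2, rmax, conc;
};

inline void deriv(const BivParams &p, const double y[2], double dy[2]) {
  const double free_sites = p.rmax - y[0] - 2.0 * y[1];
  dy[0] = 2.0 * p.ka1 * p.conc * free_sites - p.kd1 * y[0]
        - p.ka2 * y[0] * free_sites + 2.0 * p.kd2 * y[1];
  dy[1] = p.ka2 * y[0] * free_sites - 2.0 * p.kd2 * y[1];
}

// One adaptive DP45 step; returns accepted step size used, updates y and t.
void integrate_to(const BivParams &p, double &t, double t_end, double y[2],
                  double rtol, double atol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  double h = (t_end - t);
  if (h <= 0) return;
  // initial step guess from rate scale
  double scale = p.ka1 * p.conc + p.kd1 + p.ka2 * p.rmax + p.kd2 + 1e-12;
  double h0 = 0.01 / scale;
  if (h0 < h) h = h0;

  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], ynew[2];
  deriv(p, y, k1);
  int iter = 0;
  while (t < t_end && ++iter < 10000000) {
    if (t + h > t_end) h = t_end - t;
    yt[0] = y[0] + h * a21 * k1[0];
    yt[1] = y[1] + h * a21 * k1[1];
    deriv(p, yt, k2);
    yt[0] = y[0] + h * (a31 * k1[0] + a32 * k2[0]);
    yt[1] = y[1] + h * (a31 * k1[1] + a32 * k2[1]);
    deriv(p, yt, k3);
    yt[0] = y[0] + h * (a41 * k1[0] + a42 * k2[0] + a43 * k3[0]);
    yt[1] = y[1] + h * (a41 * k1[1] + a42 * k2[1] + a43 * k3[1]);
    deriv(p, yt, k4);
    yt[0] = y[0] + h * (a51 * k1[0] + a52 * k2[0] + a53 * k3[0] + a54 * k4[0]);
    yt[1] = y[1] + h * (a51 * k1[1] + a52 * k2[1] + a53 * k3[1] + a54 * k4[1]);
    deriv(p, yt, k5);
    yt[0] = y[0] + h * (a61 * k1[0] + a62 * k2[0] + a63 * k3[0] +
                        a64 * k4[0] + a65 * k5[0]);
    yt[1] = y[1] + h * (a61 * k1[1] + a62 * k2[1] + a63 * k3[1] +
                        a64 * k4[1] + a65 * k5[1]);
    deriv(p, yt, k6);
    ynew[0] = y[0] + h * (b1 * k1[0] + b3 * k3[0] + b4 * k4[0] +
                          b5 * k5[0] + b6 * k6[0]);
    ynew[1] = y[1] + h * (b1 * k1[1] + b3 * k3[1] + b4 * k4[1] +
                          b5 * k5[1] + b6 * k6[1]);
    deriv(p, ynew, k7);
    double err = 0.0;
    for (int i = 0; i < 2; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / 2.0);
    if (err <= 1.0) {
      t += h;
      y[0] = ynew[0];
      y[1] = ynew[1];
      k1[0] = k7[0];
      k1[1] = k7[1]; // FSAL
    }
    double fac = 0.9 * std::pow(err > 1e-30 ? err : 1e-30, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-12) h = 1e-12;
  }
}

} // namespace

// [[Rcpp::export(name = ".biv_ode_cpp")]]
Rcpp::NumericMatrix biv_ode_cpp(double ka1, double kd1, double ka2, double kd2,
                                double rmax, double conc,
                                Rcpp::NumericVector times, double t_assoc,
                                double rtol, double atol) {
  const int n = times.size();
  Rcpp::NumericMatrix out(n, 2); // columns R1, R2
  BivParams p{ka1, kd1, ka2, kd2, rmax, conc};
  double y[2] = {0.0, 0.0};
  double t = 0.0;
  bool dissoc = false;
  for (int i = 0; i < n; ++i) {
    double ti = times[i];
    if (!dissoc && ti > t_assoc) {
      integrate_to(p, t, t_assoc, y, rtol, atol);
      p.conc = 0.0;
      dissoc = true;
    }
    integrate_to(p, t, ti, y, rtol, atol);
    out(i, 0) = y[0];
    out(i, 1) = y[1];
  }
  return out;
}
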