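#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step classical RK4 kernels for the two clock models. The right-hand
// sides mirror the R-level goodwin_rhs()/twovar_rhs() exactly; tests assert
// the equivalence. Compiled loops keep the random-parameterization screen
// (thousands of runs at dt = 0.01) tractable.

namespace {

struct GoodwinPars {
  double vs, vm, ks, vd, k1, k2, KI, KM, KD, n;
};

inline void goodwin_deriv(const double *y, const GoodwinPars &p, double *dy) {
  double KIn = std::pow(p.KI, p.n);
  double Pn  = std::pow(y[2], p.n);
  dy[0] = p.vs * KIn / (KIn + Pn) - p.vm * y[0] / (p.KM + y[0]);
  dy[1] = p.ks * y[0] - p.vd * y[1] / (p.KD + y[1]);
  dy[2] = p.k1 * y[1] - p.k2 * y[2];
}

struct TwovarPars {
  double k, v, a, s, d, h, Kv, Ks, alpha, gamma, eps;
};

inline void twovar_deriv(const double *y, const TwovarPars &p, double *dy) {
  double Xg  = std::pow(y[0], p.gamma);
  double Kvg = std::pow(p.Kv, p.gamma);
  double Xa  = std::pow(y[0], p.alpha);
  double Ksa = std::pow(p.Ks, p.alpha);
  dy[0] = ((p.k + p.v * Xg / (Kvg + Xg)) / (p.h + y[1]) - p.a * y[0]) / p.eps;
  dy[1] = p.s * Xa / (Ksa + Xa) - p.d * y[1];
}

template <typename Pars, void (*Deriv)(const double *, const Pars &, double *)>
NumericMatrix rk4_loop(NumericVector init, const Pars &pars, double t_end,
                       double dt, int nvar) {
  int nstep = (int)std::lround(t_end / dt);
  NumericMatrix out(nstep + 1, nvar);
  std::vector<double> y(nvar), yt(nvar), k1(nvar), k2(nvar), k3(nvar), k4(nvar);
  for (int j = 0; j < nvar; ++j) { y[j] = init[j]; out(0, j) = y[j]; }
  for (int i = 0; i < nstep; ++i) {
    Deriv(y.data(), pars, k1.data());
    for (int j = 0; j < nvar; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    Deriv(yt.data(), pars, k2.data());
    for (int j = 0; j < nvar; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    Deriv(yt.data(), pars, k3.data());
    for (int j = 0; j < nvar; ++j) yt[j] = y[j] + dt * k3[j];
    Deriv(yt.data(), pars, k4.data());
    for (int j = 0; j < nvar; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      out(i + 1, j) = y[j];
    }
    if (!std::isfinite(y[0]))
      stop("integration failure: non-finite state at t = %f", (i + 1) * dt);
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".rk4_goodwin")]]
NumericMatrix rk4_goodwin(NumericVector init, List rates, List structural,
                          double t_end, double dt) {
  GoodwinPars p;
  p.vs = rates["vs"]; p.vm = rates["vm"]; p.ks = rates["ks"];
  p.vd = rates["vd"]; p.k1 = rates["k1"]; p.k2 = rates["k2"];
  p.KI = structural["KI"]; p.KM = structural["KM"];
  p.KD = structural["KD"]; p.n = structural["n"];
  return rk4_loop<GoodwinPars, goodwin_deriv>(init, p, t_end, dt, 3);
}

// [[Rcpp::export(name = ".rk4_twovar")]]
NumericMatrix rk4_twovar(NumericVector init, List rates, List structural,
                         double t_end, double dt) {
  TwovarPars p;
  p.k = rates["k"]; p.v = rates["v"]; p.a = rates["a"];
  p.s = rates["s"]; p.d = rates["d"];
  p.h = structural["h"]; p.Kv = structural["Kv"]; p.Ks = structural["Ks"];
  p.alpha = structural["alpha"]; p.gamma = structural["gamma"];
  p.eps = structural["eps"];
  if (p.eps <= 0) stop("eps must be positive");
  return rk4_loop<TwovarPars, twovar_deriv>(init, p, t_end, dt, 2);
}
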