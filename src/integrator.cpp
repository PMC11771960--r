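// Network right-hand side and adaptive Dormand-Prince 5(4) integrator.
//
// State layout: x = [ V (n units, mV), h (nb bursters, unitless),
//                     chiL, chiR (stance-phase clocks, unitless) ].
// All structural information (weights, drives, feedback entry weights with
// presynaptic gains already folded in) is compiled on the R side into the
// flat parameter list consumed here; see compile_network().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Net {
  int n;                       // number of units
  int nb;                      // number of bursters
  std::vector<double> Cap, gL, EL;
  std::vector<int> bidx;       // unit index (0-based) of each burster
  std::vector<double> gNaP, ENa, th_m, sg_m, th_h, sg_h, tau0;
  std::vector<double> WE, WI;  // n x n, row-major: W[i*n + j] = weight j -> i
  std::vector<double> dE, dI;  // constant drive-derived conductances
  std::vector<double> FBE, FBI;// n x 4 feedback weights (gain folded), cols:
                               // SF-E1_L, SF-E1_R, SF-E2_L, SF-E2_R
  double ESynE, ESynI;
  int iFL, iFR, iEL, iER;      // flexor/extensor unit indices, -1 if absent
  double kE1, kE2, betaL, betaR, Tramp, tauReset;
  double Vthr, Vmax;
};

inline double outf(double V, double Vthr, double Vmax) {
  if (V <= Vthr) return 0.0;
  if (V >= Vmax) return 1.0;
  return (V - Vthr) / (Vmax - Vthr);
}

Net unpack(const List& par) {
  Net nt;
  nt.n   = as<int>(par["n"]);
  nt.Cap = as<std::vector<double> >(par["C"]);
  nt.gL  = as<std::vector<double> >(par["gL"]);
  nt.EL  = as<std::vector<double> >(par["EL"]);
  nt.bidx = as<std::vector<int> >(par["bidx"]);
  nt.nb  = (int) nt.bidx.size();
  nt.gNaP = as<std::vector<double> >(par["gNaP"]);
  nt.ENa  = as<std::vector<double> >(par["ENa"]);
  nt.th_m = as<std::vector<double> >(par["theta_m"]);
  nt.sg_m = as<std::vector<double> >(par["sigma_m"]);
  nt.th_h = as<std::vector<double> >(par["theta_h"]);
  nt.sg_h = as<std::vector<double> >(par["sigma_h"]);
  nt.tau0 = as<std::vector<double> >(par["tau0"]);
  nt.WE = as<std::vector<double> >(par["WE"]);
  nt.WI = as<std::vector<double> >(par["WI"]);
  nt.dE = as<std::vector<double> >(par["dE"]);
  nt.dI = as<std::vector<double> >(par["dI"]);
  nt.FBE = as<std::vector<double> >(par["FBE"]);
  nt.FBI = as<std::vector<double> >(par["FBI"]);
  nt.ESynE = as<double>(par["ESynE"]);
  nt.ESynI = as<double>(par["ESynI"]);
  nt.iFL = as<int>(par["iFL"]);
  nt.iFR = as<int>(par["iFR"]);
  nt.iEL = as<int>(par["iEL"]);
  nt.iER = as<int>(par["iER"]);
  nt.kE1 = as<double>(par["kE1"]);
  nt.kE2 = as<double>(par["kE2"]);
  nt.betaL = as<double>(par["betaL"]);
  nt.betaR = as<double>(par["betaR"]);
  nt.Tramp = as<double>(par["Tramp"]);
  nt.tauReset = as<double>(par["tauReset"]);
  nt.Vthr = as<double>(par["Vthr"]);
  nt.Vmax = as<double>(par["Vmax"]);
  return nt;
}

// dx must have length n + nb + 2
void rhs(const Net& nt, const double* x, double* dx,
         std::vector<double>& out) {
  const int n = nt.n, nb = nt.nb;
  const double chiL = x[n + nb], chiR = x[n + nb + 1];

  for (int i = 0; i < n; ++i) out[i] = outf(x[i], nt.Vthr, nt.Vmax);

  const double fEL = (nt.iEL >= 0) ? out[nt.iEL] : 0.0;
  const double fER = (nt.iER >= 0) ? out[nt.iER] : 0.0;

  // Feedback signals: SF-E1 ramps with time-in-stance and belt speed,
  // SF-E2 follows extensor output; both vanish when the extensor is silent.
  double u[4];
  u[0] = (fEL > 0.0) ? nt.kE1 * nt.betaL * std::min(chiL, 1.0) : 0.0;
  u[1] = (fER > 0.0) ? nt.kE1 * nt.betaR * std::min(chiR, 1.0) : 0.0;
  u[2] = nt.kE2 * fEL;
  u[3] = nt.kE2 * fER;

  // which burster (if any) each unit is: -1 or index into h
  for (int i = 0; i < n; ++i) {
    double gE = nt.dE[i], gI = nt.dI[i];
    const double* we = &nt.WE[(size_t)i * n];
    const double* wi = &nt.WI[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      gE += we[j] * out[j];
      gI += wi[j] * out[j];
    }
    for (int s = 0; s < 4; ++s) {
      gE += nt.FBE[(size_t)i * 4 + s] * u[s];
      gI += nt.FBI[(size_t)i * 4 + s] * u[s];
    }
    const double V = x[i];
    double I = -nt.gL[i] * (V - nt.EL[i])
               - gE * (V - nt.ESynE)
               - gI * (V - nt.ESynI);
    dx[i] = I;  // divide by C after possible NaP term
  }

  for (int b = 0; b < nb; ++b) {
    const int i = nt.bidx[b];
    const double V = x[i], h = x[n + b];
    const double minf =
        1.0 / (1.0 + std::exp(-(V - nt.th_m[b]) / nt.sg_m[b]));
    const double hinf =
        1.0 / (1.0 + std::exp((V - nt.th_h[b]) / nt.sg_h[b]));
    const double tauh =
        nt.tau0[b] / std::cosh((V - nt.th_h[b]) / (2.0 * nt.sg_h[b]));
    dx[i] += -nt.gNaP[b] * minf * h * (V - nt.ENa[b]);
    dx[n + b] = (hinf - h) / (tauh / 1000.0);  // tau0 in ms, time in s
  }

  for (int i = 0; i < n; ++i)
    dx[i] = dx[i] / nt.Cap[i] * 1000.0;  // pF, nS, mV -> mV/s

  // stance-phase clocks: ramp while the ipsilateral flexor is silent
  // (extension), exponential reset while it is active (continuous
  // stand-in for a hard reset at flexion onset)
  const double fFL = (nt.iFL >= 0) ? out[nt.iFL] : 0.0;
  const double fFR = (nt.iFR >= 0) ? out[nt.iFR] : 0.0;
  dx[n + nb]     = (fFL <= 0.0) ? ((chiL < 2.0) ? 1.0 / nt.Tramp : 0.0)
                                : -chiL / nt.tauReset;
  dx[n + nb + 1] = (fFR <= 0.0) ? ((chiR < 2.0) ? 1.0 / nt.Tramp : 0.0)
                                : -chiR / nt.tauReset;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "net_rhs_cpp")]]
NumericVector net_rhs_cpp(NumericVector x, List par) {
  Net nt = unpack(par);
  const int nx = nt.n + nt.nb + 2;
  if ((int)x.size() != nx) stop("state vector has wrong length");
  NumericVector dx(nx);
  std::vector<double> out(nt.n);
  rhs(nt, x.begin(), dx.begin(), out);
  return dx;
}

// Dormand-Prince 5(4) with standard coefficients.
// [[Rcpp::export(name = "net_integrate_cpp")]]
List net_integrate_cpp(NumericVector x0, double t0, double t1, double dt_out,
                       List par, double rtol, double atol, double hmax) {
  Net nt = unpack(par);
  const int n = nt.n, nb = nt.nb;
  const int nx = n + nb + 2;
  if ((int)x0.size() != nx) stop("initial state has wrong length");

  static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
  static const double a21 = 1.0/5;
  static const double a31 = 3.0/40, a32 = 9.0/40;
  static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
  static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                      a53 = 64448.0/6561, a54 = -212.0/729;
  static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                      a64 = 49.0/176, a65 = -5103.0/18656;
  static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                      b5 = -2187.0/6784, b6 = 11.0/84;
  static const double e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
                      e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40;

  const int nout = (int) std::floor((t1 - t0) / dt_out + 0.5) + 1;
  NumericMatrix X(nout, nx);
  NumericVector tout(nout);
  for (int k = 0; k < nout; ++k) tout[k] = t0 + k * dt_out;

  std::vector<double> y(x0.begin(), x0.end());
  std::vector<double> k1(nx), k2(nx), k3(nx), k4(nx), k5(nx), k6(nx), k7(nx);
  std::vector<double> ytmp(nx), ynew(nx), out(n);
  const double hmin = 1e-9;
  long nsteps = 0, nreject = 0, nforced = 0;

  for (int j = 0; j < nx; ++j) X(0, j) = y[j];

  double t = t0;
  double hstep = std::min(hmax, dt_out);
  bool have_k1 = false;

  for (int k = 1; k < nout; ++k) {
    const double tend = tout[k];
    while (t < tend - 1e-12) {
      double h = std::min(hstep, tend - t);
      if (!have_k1) { rhs(nt, y.data(), k1.data(), out); have_k1 = true; }

      for (int j = 0; j < nx; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      rhs(nt, ytmp.data(), k2.data(), out);
      for (int j = 0; j < nx; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      rhs(nt, ytmp.data(), k3.data(), out);
      for (int j = 0; j < nx; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      rhs(nt, ytmp.data(), k4.data(), out);
      for (int j = 0; j < nx; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j]
                              + a54 * k4[j]);
      rhs(nt, ytmp.data(), k5.data(), out);
      for (int j = 0; j < nx; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j]
                              + a64 * k4[j] + a65 * k5[j]);
      rhs(nt, ytmp.data(), k6.data(), out);
      for (int j = 0; j < nx; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j]
                              + b5 * k5[j] + b6 * k6[j]);
      rhs(nt, ynew.data(), k7.data(), out);

      double err = 0.0;
      for (int j = 0; j < nx; ++j) {
        const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j]
                               + e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double sc = atol + rtol * std::max(std::fabs(y[j]),
                                                 std::fabs(ynew[j]));
        const double r = ej / sc;
        err += r * r;
      }
      err = std::sqrt(err / nx);
      if (!std::isfinite(err)) {
        stop("solver blow-up: non-finite state at t = %f s", t);
      }

      if (err <= 1.0 || h <= hmin * 2.0) {
        if (err > 1.0) ++nforced;
        t += h;
        y.swap(ynew);
        // FSAL: k7 at ynew is k1 of the next step
        k1.swap(k7);
        // clamp h-variables and clocks to their invariant ranges
        bool clamped = false;
        for (int b = 0; b < nb; ++b) {
          double& hb = y[n + b];
          if (hb < 0.0) { hb = 0.0; clamped = true; }
          if (hb > 1.0) { hb = 1.0; clamped = true; }
        }
        for (int c = 0; c < 2; ++c) {
          double& ch = y[n + nb + c];
          if (ch < 0.0) { ch = 0.0; clamped = true; }
        }
        if (clamped) have_k1 = false; else have_k1 = true;
        ++nsteps;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        fac = std::min(5.0, std::max(0.2, fac));
        hstep = std::min(hmax, h * fac);
      } else {
        ++nreject;
        double fac = 0.9 * std::pow(err, -0.2);
        fac = std::min(1.0, std::max(0.1, fac));
        hstep = std::max(hmin, h * fac);
        // k1 still valid at y
      }
      if (nsteps + nreject > 200000000L)
        stop("solver exceeded step budget at t = %f s", t);
    }
    t = tend;
    for (int j = 0; j < nx; ++j) X(k, j) = y[j];
  }

  return List::create(_["time"] = tout, _["states"] = X,
                      _["nsteps"] = (double) nsteps,
                      _["nreject"] = (double) nreject,
                      _["nforced"] = (double) nforced);
}
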