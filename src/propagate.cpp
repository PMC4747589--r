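#include <Rcpp.h>
using namespace Rcpp;

// Exact propagation of the linear gene-expression system
//   dm/dt = km * u(t) - gm * m
//   dp/dt = kp * m    - gp * p
// over a grid on which u is piecewise constant: u[k] holds on
// [times[k], times[k+1]). Each segment is advanced with the closed-form
// solution; the only numerically delicate term is
//   Phi = (exp(-gm*dt) - exp(-gp*dt)) / (gp - gm)
// which is evaluated as exp(-gm*dt) * (-expm1(-(gp-gm)*dt)) / (gp-gm)
// to avoid cancellation, with the gp == gm limit dt * exp(-g*dt).
// [[Rcpp::export]]
List cpp_propagate(NumericVector times, NumericVector u,
                   double km, double gm, double kp, double gp,
                   double m0, double p0) {
  int n = times.size();
  if (u.size() != n - 1)
    stop("length(u) must be length(times) - 1");
  NumericVector m(n), p(n);
  m[0] = m0;
  p[0] = p0;
  double dg = gp - gm;
  for (int k = 0; k < n - 1; ++k) {
    double dt = times[k + 1] - times[k];
    double A  = km * u[k] / gm;          // segment steady state of m
    double Em = std::exp(-gm * dt);
    double Ep = std::exp(-gp * dt);
    double B  = m[k] - A;
    double x  = dg * dt;
    double Phi = (x == 0.0) ? dt * Em : Em * (-std::expm1(-x)) / dg;
    m[k + 1] = A + B * Em;
    p[k + 1] = p[k] * Ep + (kp * A / gp) * (1.0 - Ep) + kp * B * Phi;
  }
  return List::create(_["m"] = m, _["p"] = p);
}

// Same propagation, returning only the protein level at selected grid
// indices (1-based, non-decreasing, duplicates allowed). This is the hot
// path of the likelihood: it avoids materializing full trajectories inside
// MCMC / optimization loops. When reset_idx > 1 the protein level is reset
// to p0 on reaching that grid index: this anchors p at a cell's first
// observation while the mRNA level is still propagated from the start of
// the stimulus history (where m = 0 holds exactly).
// [[Rcpp::export]]
NumericVector cpp_predict(NumericVector times, NumericVector u,
                          double km, double gm, double kp, double gp,
                          double m0, double p0, IntegerVector qidx,
                          int reset_idx = 1) {
  int n = times.size();
  if (u.size() != n - 1)
    stop("length(u) must be length(times) - 1");
  int nq = qidx.size();
  NumericVector out(nq);
  double m = m0, p = p0;
  double dg = gp - gm;
  int j = 0;
  while (j < nq && qidx[j] == 1) out[j++] = p;
  for (int k = 0; k < n - 1 && j < nq; ++k) {
    double dt = times[k + 1] - times[k];
    double A  = km * u[k] / gm;
    double Em = std::exp(-gm * dt);
    double Ep = std::exp(-gp * dt);
    double B  = m - A;
    double x  = dg * dt;
    double Phi = (x == 0.0) ? dt * Em : Em * (-std::expm1(-x)) / dg;
    m = A + B * Em;
    p = p * Ep + (kp * A / gp) * (1.0 - Ep) + kp * B * Phi;
    if (k + 2 == reset_idx) p = p0;
    while (j < nq && qidx[j] == k + 2) out[j++] = p;
  }
  return out;
}

static inline void deriv(double uval, double km, double gm, double kp,
                         double gp, double m, double p,
                         double &dm, double &dp) {
  dm = km * uval - gm * m;
  dp = kp * m - gp * p;
}

// Fixed-step classical Runge-Kutta reference integrator over the same
// piecewise-constant input. Each inter-breakpoint segment is covered with
// uniform substeps of length <= h so that steps never straddle a
// discontinuity of u. Used as an independent oracle for cpp_propagate.
// [[Rcpp::export]]
List cpp_rk4(NumericVector times, NumericVector u,
             double km, double gm, double kp, double gp,
             double m0, double p0, double h) {
  int n = times.size();
  if (u.size() != n - 1)
    stop("length(u) must be length(times) - 1");
  if (h <= 0.0)
    stop("h must be positive");
  NumericVector m(n), p(n);
  double mc = m0, pc = p0;
  m[0] = mc;
  p[0] = pc;
  for (int k = 0; k < n - 1; ++k) {
    double seg = times[k + 1] - times[k];
    int nstep = (int)std::ceil(seg / h - 1e-12);
    if (nstep < 1) nstep = 1;
    double hh = seg / nstep;
    double uval = u[k];
    for (int s = 0; s < nstep; ++s) {
      double k1m, k1p, k2m, k2p, k3m, k3p, k4m, k4p;
      deriv(uval, km, gm, kp, gp, mc, pc, k1m, k1p);
      deriv(uval, km, gm, kp, gp, mc + 0.5 * hh * k1m, pc + 0.5 * hh * k1p,
            k2m, k2p);
      deriv(uval, km, gm, kp, gp, mc + 0.5 * hh * k2m, pc + 0.5 * hh * k2p,
            k3m, k3p);
      deriv(uval, km, gm, kp, gp, mc + hh * k3m, pc + hh * k3p, k4m, k4p);
      mc += hh / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
      pc += hh / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
    }
    m[k + 1] = mc;
    p[k + 1] = pc;
  }
  return List::create(_["m"] = m, _["p"] = p);
}
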