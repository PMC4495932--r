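// Fixed-step integration of the homeostatic rate model
//
//   tau1 dr1/dt = -r1 + g(V r1 + u(t) + eta(t) - h * r3)
//   tau2 dr2/dt = -r2 + r1
//   tau3 dr3/dt =  r2 - r_goal          (perfect integrator)
//
// Deterministic runs use classic RK4; with input noise an Euler-Maruyama
// step is used, the Ornstein-Uhlenbeck input being advanced with its exact
// one-step update.  All time constants in ms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// piecewise-constant input u(t), breakpoints ascending
double step_input(double t, const arma::vec& times, const arma::vec& vals) {
  if (times.n_elem == 0) return 0.0;
  // last breakpoint with times[i] <= t
  arma::uword lo = 0, hi = times.n_elem;
  while (lo < hi) {
    arma::uword mid = (lo + hi) / 2;
    if (times[mid] <= t) lo = mid + 1; else hi = mid;
  }
  if (lo == 0) return 0.0;
  return vals[lo - 1];
}

struct FICurve {
  int kind; // 0 linear, 1 threshold-linear, 2 sigmoid, 3 tabulated
  arma::vec par;
  arma::vec tx, ty;
  double eval(double x) const {
    switch (kind) {
    case 0: return par[0] * x;
    case 1: return x > par[1] ? par[0] * (x - par[1]) : 0.0;
    case 2: return par[0] / (1.0 + std::exp(-(x - par[1]) / par[2]));
    default: { // tabulated, linear interpolation, clamped
      if (x <= tx[0]) return ty[0];
      arma::uword n = tx.n_elem;
      if (x >= tx[n - 1]) return ty[n - 1];
      arma::uword lo = 0, hi = n - 1;
      while (hi - lo > 1) {
        arma::uword mid = (lo + hi) / 2;
        if (tx[mid] <= x) lo = mid; else hi = mid;
      }
      double w = (x - tx[lo]) / (tx[hi] - tx[lo]);
      return ty[lo] + w * (ty[hi] - ty[lo]);
    }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List rate_sim_cpp(const arma::mat& V,
                  const arma::vec& tau1, const arma::vec& tau2,
                  const arma::vec& tau3, double rgoal,
                  int fi_kind, const arma::vec& fi_par,
                  const arma::vec& fi_x, const arma::vec& fi_y,
                  const arma::vec& u_times, const arma::vec& u_vals,
                  double noise_sigma, double noise_tau,
                  double dt, int nsteps, int stride,
                  bool rectify, double hgain, bool integrate_r3,
                  const arma::vec& r1_0, const arma::vec& r2_0,
                  const arma::vec& r3_0) {
  const arma::uword N = V.n_rows;
  FICurve g{fi_kind, fi_par, fi_x, fi_y};

  arma::vec r1 = r1_0, r2 = r2_0, r3 = r3_0;
  arma::vec eta(N, arma::fill::zeros);
  const bool noisy = noise_sigma > 0.0;
  const double ou_decay = noisy ? std::exp(-dt / noise_tau) : 0.0;
  const double ou_kick  = noisy ? noise_sigma * std::sqrt(1.0 - ou_decay * ou_decay) : 0.0;

  const int nrec = nsteps / stride + 1;
  arma::mat R1(N, nrec), R2(N, nrec), R3(N, nrec);
  arma::vec tgrid(nrec);
  int rec = 0;
  bool truncated = false;

  arma::vec drive(N), k1r1(N), k1r2(N), k1r3(N), k2r1(N), k2r2(N), k2r3(N),
      k3r1(N), k3r2(N), k3r3(N), k4r1(N), k4r2(N), k4r3(N),
      x(N), a1(N), a2(N), a3(N);

  auto deriv = [&](const arma::vec& y1, const arma::vec& y2, const arma::vec& y3,
                   double t, arma::vec& d1, arma::vec& d2, arma::vec& d3) {
    double u = step_input(t, u_times, u_vals);
    x = V * y1 + u;
    if (noisy) x += eta;
    if (hgain != 0.0) x -= hgain * y3;
    for (arma::uword i = 0; i < N; ++i) drive[i] = g.eval(x[i]);
    d1 = (-y1 + drive) / tau1;
    d2 = (-y2 + y1) / tau2;
    if (integrate_r3) d3 = (y2 - rgoal) / tau3; else d3.zeros();
  };

  R1.col(0) = r1; R2.col(0) = r2; R3.col(0) = r3; tgrid[0] = 0.0; rec = 1;

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    if (noisy) {
      for (arma::uword i = 0; i < N; ++i)
        eta[i] = ou_decay * eta[i] + ou_kick * R::norm_rand();
      // Euler-Maruyama
      deriv(r1, r2, r3, t, k1r1, k1r2, k1r3);
      r1 += dt * k1r1; r2 += dt * k1r2; r3 += dt * k1r3;
    } else {
      deriv(r1, r2, r3, t, k1r1, k1r2, k1r3);
      a1 = r1 + 0.5 * dt * k1r1; a2 = r2 + 0.5 * dt * k1r2; a3 = r3 + 0.5 * dt * k1r3;
      deriv(a1, a2, a3, t + 0.5 * dt, k2r1, k2r2, k2r3);
      a1 = r1 + 0.5 * dt * k2r1; a2 = r2 + 0.5 * dt * k2r2; a3 = r3 + 0.5 * dt * k2r3;
      deriv(a1, a2, a3, t + 0.5 * dt, k3r1, k3r2, k3r3);
      a1 = r1 + dt * k3r1; a2 = r2 + dt * k3r2; a3 = r3 + dt * k3r3;
      deriv(a1, a2, a3, t + dt, k4r1, k4r2, k4r3);
      r1 += dt / 6.0 * (k1r1 + 2.0 * k2r1 + 2.0 * k3r1 + k4r1);
      r2 += dt / 6.0 * (k1r2 + 2.0 * k2r2 + 2.0 * k3r2 + k4r2);
      r3 += dt / 6.0 * (k1r3 + 2.0 * k2r3 + 2.0 * k3r3 + k4r3);
    }
    if (rectify) r1.transform([](double v) { return v < 0.0 ? 0.0 : v; });

    if (!r1.is_finite() || !r3.is_finite()) { truncated = true; break; }

    if ((s + 1) % stride == 0 && rec < nrec) {
      R1.col(rec) = r1; R2.col(rec) = r2; R3.col(rec) = r3;
      tgrid[rec] = (s + 1) * dt;
      ++rec;
    }
  }

  if (rec < nrec) {
    R1 = R1.cols(0, rec - 1); R2 = R2.cols(0, rec - 1);
    R3 = R3.cols(0, rec - 1); tgrid = tgrid.subvec(0, rec - 1);
  }

  return List::create(_["time"] = tgrid, _["r1"] = R1, _["r2"] = R2,
                      _["r3"] = R3, _["truncated"] = truncated);
}
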