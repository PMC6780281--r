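// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

//' Integrate the two-element Windkessel dP/dt = Q(t)/C - P/(R C) with
//' fixed-step classical RK4.
//'
//' @param flow ejection flow (mL/s) sampled on the half-step grid: value
//'   2*i is at t = i*dt, value 2*i+1 at t = (i+1/2)*dt; length 2*n + 1.
//' @param resistance per-step resistance (mmHg*s/mL), length n; held
//'   constant within each step (it changes only at beat boundaries).
//' @param compliance arterial compliance, mL/mmHg.
//' @param dt step, seconds.
//' @param p0 initial pressure, mmHg.
//' @return pressure at the step grid, length n + 1.
//' @keywords internal
// [[Rcpp::export]]
arma::vec wk_rk4(const arma::vec& flow, const arma::vec& resistance,
                 double compliance, double dt, double p0) {
  const arma::uword n = resistance.n_elem;
  if (flow.n_elem != 2 * n + 1)
    Rcpp::stop("flow must have length 2*length(resistance) + 1");
  if (compliance <= 0.0) Rcpp::stop("compliance must be positive");
  arma::vec p(n + 1);
  p[0] = p0;
  const double invC = 1.0 / compliance;
  for (arma::uword i = 0; i < n; ++i) {
    const double tau = resistance[i] * compliance;
    const double a = 1.0 / tau;
    const double q0 = flow[2 * i], qh = flow[2 * i + 1], q1 = flow[2 * i + 2];
    const double pi = p[i];
    const double k1 = q0 * invC - a * pi;
    const double k2 = qh * invC - a * (pi + 0.5 * dt * k1);
    const double k3 = qh * invC - a * (pi + 0.5 * dt * k2);
    const double k4 = q1 * invC - a * (pi + dt * k3);
    p[i + 1] = pi + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return p;
}
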