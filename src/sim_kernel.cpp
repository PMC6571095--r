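// Euler-Maruyama integration of the rate / synaptic-gating / depression
// dynamics.  Time is in ms throughout; rates in Hz, so every r*tau product
// inside the synaptic equations converts tau to seconds.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".simulate_kernel")]]
List simulate_kernel(const arma::mat& Wt,          // Wt(j,i) = W(i,j): I = Wt * s
                     const arma::vec& r0, const arma::vec& s0, const arma::vec& D0,
                     const arma::vec& tau_s, const arma::vec& theta,
                     const arma::vec& delta, const arma::vec& p0,
                     const arma::vec& rmax,
                     double tau_r, double tau_D, double alpha,
                     const arma::vec& pulse_start, const arma::vec& pulse_end,
                     const arma::mat& pulse_cur,   // n x n_pulses
                     double dt, double t_end, double noise_sd,
                     unsigned int seed, int record_stride,
                     double avg_start, double avg_end, bool clamp_D) {
  const arma::uword n = r0.n_elem;
  if (Wt.n_rows != n || Wt.n_cols != n)
    stop("structural error: weight matrix is %dx%d but state has %d units",
         (int)Wt.n_rows, (int)Wt.n_cols, (int)n);

  arma::vec r = r0, s = s0, D = D0;
  const int n_steps = (int)std::lround(t_end / dt);
  const double tol = 1e-9;
  const arma::vec tau_s_sec = tau_s / 1000.0;
  const double tau_D_sec = tau_D / 1000.0;

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const int n_pulses = (int)pulse_start.n_elem;
  int pulse_idx = 0;

  const bool record = record_stride > 0;
  int n_rec = record ? (n_steps / record_stride + 1) : 0;
  arma::mat traj_r, traj_s, traj_D;
  arma::vec traj_t;
  if (record) {
    traj_r.set_size(n, n_rec); traj_s.set_size(n, n_rec); traj_D.set_size(n, n_rec);
    traj_t.set_size(n_rec);
  }
  int rec_i = 0;

  arma::vec rate_sum(n, arma::fill::zeros);
  long avg_count = 0;

  arma::vec I(n);
  const double dt_tau_r = dt / tau_r;
  const double dt_tau_D = dt / tau_D;
  const arma::vec dt_tau_s = dt / tau_s;

  for (int k = 0; k <= n_steps; ++k) {
    double t = k * dt;

    if (record && (k % record_stride == 0) && rec_i < n_rec) {
      traj_r.col(rec_i) = r; traj_s.col(rec_i) = s; traj_D.col(rec_i) = D;
      traj_t[rec_i] = t; ++rec_i;
    }
    if (avg_end > avg_start && t >= avg_start && t < avg_end) {
      rate_sum += r; ++avg_count;
    }
    if (k == n_steps) break;

    // applied current: pulses are sorted and non-overlapping
    I = Wt * s;
    while (pulse_idx < n_pulses && t >= pulse_end[pulse_idx]) ++pulse_idx;
    if (pulse_idx < n_pulses && t >= pulse_start[pulse_idx] && t < pulse_end[pulse_idx])
      I += pulse_cur.col(pulse_idx);
    if (noise_sd > 0.0)
      for (arma::uword j = 0; j < n; ++j) I[j] += noise_sd * gauss(rng);

    // fused Euler update; tiny overshoots of [0, 1] are clipped, larger
    // violations abort with the offending unit
    for (arma::uword j = 0; j < n; ++j) {
      double ex = (theta[j] - I[j]) / delta[j];
      ex = ex > 500.0 ? 500.0 : (ex < -500.0 ? -500.0 : ex);
      double f = rmax[j] / (1.0 + std::exp(ex));
      double pr = p0[j] * r[j] * D[j];
      double x = alpha * pr * tau_s_sec[j];
      double r_new = r[j] + dt_tau_r * (f - r[j]);
      double s_new = s[j] + dt_tau_s[j] * (x * (1.0 - s[j]) - s[j]);
      double D_new = clamp_D ? D[j]
        : D[j] + dt_tau_D * (1.0 - D[j] - tau_D_sec * pr);
      if (s_new > 1.0 || s_new < 0.0 || D_new > 1.0 || D_new < 0.0 ||
          !std::isfinite(r_new)) {
        if (!std::isfinite(r_new))
          stop("integration error: rate of unit %d is not finite at t = %g ms",
               (int)(j + 1), t);
        if (s_new > 1.0 && s_new - 1.0 < tol) s_new = 1.0;
        else if (s_new < 0.0 && -s_new < tol) s_new = 0.0;
        if (D_new > 1.0 && D_new - 1.0 < tol) D_new = 1.0;
        else if (D_new < 0.0 && -D_new < tol) D_new = 0.0;
        if (s_new > 1.0 || s_new < 0.0)
          stop("integration error: gating variable s of unit %d left [0, 1] (value %g)",
               (int)(j + 1), s_new);
        if (D_new > 1.0 || D_new < 0.0)
          stop("integration error: depression variable D of unit %d left [0, 1] (value %g)",
               (int)(j + 1), D_new);
      }
      r[j] = r_new; s[j] = s_new; D[j] = D_new;
    }
  }

  if (!r.is_finite() || !s.is_finite() || !D.is_finite())
    stop("integration error: non-finite state at end of simulation");

  List out = List::create(
    _["r"] = r, _["s"] = s, _["D"] = D, _["t"] = (double)n_steps * dt,
    _["mean_r"] = (avg_count > 0) ? NumericVector(wrap(rate_sum / (double)avg_count))
                                  : NumericVector(0),
    _["n_steps"] = n_steps);
  if (record) {
    out["traj_t"] = traj_t.head(rec_i);
    out["traj_r"] = traj_r.cols(0, rec_i - 1);
    out["traj_s"] = traj_s.cols(0, rec_i - 1);
    out["traj_D"] = traj_D.cols(0, rec_i - 1);
  }
  return out;
}
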