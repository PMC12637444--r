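// Forward-Euler integrators for the excitatory-inhibitory rate networks.
//
// All heavy per-timestep loops live here; weight construction, stimulus
// rendering and every analysis step stay in R. Conventions shared with the
// R side:
//   * time step t (0-based) covers [t*dt, (t+1)*dt); recorded rates at
//     column t are the post-update values attained during that step, so
//     column t of a recording is labelled with time t*dt after session start
//     (column 0 = response during the first integration step).
//   * STD resource traces are recorded pre-update (the value that actually
//     gated transmission during the step).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec relu(const vec& z) {
  return clamp(z, 0.0, datum::inf);
}

// STD resource dynamics x' = (1 - x)/tau_x - x * u, forward Euler.
// u: (channels x T) non-negative drive. Returns (channels x T) trace of the
// resource value used at each step; x(0) = 1.
// [[Rcpp::export]]
arma::mat cpp_std_trace(const arma::mat& u, double dt, double tau_x) {
  const uword C = u.n_rows, T = u.n_cols;
  mat X(C, T);
  vec x(C, fill::ones);
  for (uword t = 0; t < T; ++t) {
    X.col(t) = x;
    x += dt * ((1.0 - x) / tau_x - x % u.col(t));
  }
  return X;
}

// One E/I region driven by precomputed external input currents.
//   tau rE' = -rE + f(WEE rE - WIE rI + extE)
//   tau rI' = -rI + f(WEI rE - WII rI + extI)
// extE: nE x T, extI: nI x T. r(0) = 0.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_region(const arma::mat& WEE, const arma::mat& WEI,
                               const arma::mat& WIE, const arma::mat& WII,
                               const arma::mat& extE, const arma::mat& extI,
                               double dt, double tau) {
  const uword nE = WEE.n_rows, nI = WII.n_rows, T = extE.n_cols;
  if (extI.n_cols != T) Rcpp::stop("external drives disagree on length");
  mat RE(nE, T), RI(nI, T);
  vec rE(nE, fill::zeros), rI(nI, fill::zeros);
  const double a = dt / tau;
  for (uword t = 0; t < T; ++t) {
    vec dE = WEE * rE - WIE * rI + extE.col(t);
    vec dI = WEI * rE - WII * rI + extI.col(t);
    rE += a * (relu(dE) - rE);
    rI += a * (relu(dI) - rI);
    if (!rE.is_finite() || !rI.is_finite())
      Rcpp::stop("non-finite rates at timestep %u", (unsigned)(t + 1));
    RE.col(t) = rE;
    RI.col(t) = rI;
  }
  return Rcpp::List::create(Rcpp::Named("r_E") = RE, Rcpp::Named("r_I") = RI);
}

// Closed-loop frontal region of the active model. Feedforward drive
// ff = W12 * r1E is precomputed (the sensory region is feedback-free).
// Readout y = g_out * Wout * rE is fed back through depressing synapses:
//   drive_E += Wfb * (xy % y_prev);  xy' = (1 - xy)/tau_xy - xy * max(0, y_prev)
// y_prev is the readout emitted on the previous step (y(0) = 0), so the
// feedback at step t carries the signal concurrently transmitted at t.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_active(const arma::mat& WEE, const arma::mat& WEI,
                               const arma::mat& WIE, const arma::mat& WII,
                               const arma::mat& ff, const arma::mat& Wfb,
                               const arma::mat& Wout, double g_out,
                               double dt, double tau, double tau_xy) {
  const uword nE = WEE.n_rows, nI = WII.n_rows, T = ff.n_cols;
  const uword K = Wfb.n_cols;  // readout channels (2)
  mat RE(nE, T), RI(nI, T), Y(K, T), XY(K, T);
  vec rE(nE, fill::zeros), rI(nI, fill::zeros);
  vec xy(K, fill::ones), y_prev(K, fill::zeros);
  const double a = dt / tau;
  for (uword t = 0; t < T; ++t) {
    vec dE = WEE * rE - WIE * rI + ff.col(t) + Wfb * (xy % y_prev);
    vec dI = WEI * rE - WII * rI;
    rE += a * (relu(dE) - rE);
    rI += a * (relu(dI) - rI);
    if (!rE.is_finite() || !rI.is_finite())
      Rcpp::stop("non-finite rates at timestep %u", (unsigned)(t + 1));
    vec y = g_out * (Wout * rE);
    RE.col(t) = rE;
    RI.col(t) = rI;
    Y.col(t) = y;
    XY.col(t) = xy;
    xy += dt * ((1.0 - xy) / tau_xy - xy % relu(y_prev));
    y_prev = y;
  }
  return Rcpp::List::create(Rcpp::Named("r_E") = RE, Rcpp::Named("r_I") = RI,
                            Rcpp::Named("y") = Y, Rcpp::Named("x_y") = XY);
}

// FORCE training pass over one session: teacher-forced feedback (ytilde
// replaces y on the depressing feedback path) and an RLS update of Wout
// every `stride` steps. Wout and P are carried across sessions by the
// caller. Returns the updated Wout, P and a per-step mean-absolute-error
// log (subsampled every `stride` steps).
// [[Rcpp::export]]
Rcpp::List cpp_force_train(const arma::mat& WEE, const arma::mat& WEI,
                           const arma::mat& WIE, const arma::mat& WII,
                           const arma::mat& ff, const arma::mat& Wfb,
                           const arma::mat& ytilde,
                           arma::mat Wout, arma::mat P, double g_out,
                           double dt, double tau, double tau_xy, int stride) {
  const uword nE = WEE.n_rows, nI = WII.n_rows, T = ff.n_cols;
  const uword K = Wfb.n_cols;
  if (ytilde.n_cols != T) Rcpp::stop("teacher signal disagrees with drive length");
  if (stride < 1) Rcpp::stop("stride must be >= 1");
  vec rE(nE, fill::zeros), rI(nI, fill::zeros), xy(K, fill::ones);
  std::vector<double> errlog;
  errlog.reserve(T / stride + 1);
  const double a = dt / tau;
  for (uword t = 0; t < T; ++t) {
    vec yt = ytilde.col(t);
    vec dE = WEE * rE - WIE * rI + ff.col(t) + Wfb * (xy % yt);
    vec dI = WEI * rE - WII * rI;
    rE += a * (relu(dE) - rE);
    rI += a * (relu(dI) - rI);
    if (!rE.is_finite() || !rI.is_finite())
      Rcpp::stop("non-finite rates at timestep %u", (unsigned)(t + 1));
    if (t % (uword)stride == 0) {
      // RLS: error with pre-update Wout, P updated before the weight step.
      vec e = g_out * (Wout * rE) - yt;
      vec Pr = P * rE;
      double denom = 1.0 + dot(rE, Pr);
      P -= (Pr * Pr.t()) / denom;
      P = 0.5 * (P + P.t());  // suppress asymmetry drift
      vec k = P * rE;         // equals Pr/denom up to round-off
      Wout -= e * k.t();
      if (!Wout.is_finite() || norm(Wout, "fro") > 1e8)
        Rcpp::stop("FORCE training diverged at timestep %u", (unsigned)(t + 1));
      errlog.push_back(mean(abs(e)));
    }
    xy += dt * ((1.0 - xy) / tau_xy - xy % relu(yt));
  }
  return Rcpp::List::create(Rcpp::Named("W_out") = Wout, Rcpp::Named("P") = P,
                            Rcpp::Named("error_log") = errlog);
}
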