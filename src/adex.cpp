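// Discrete-time AdEx spiking network: forward simulation and the
// reverse-mode (adjoint) accumulation of the surrogate-gradient
// sensitivity recursions.  All quantities are the dimensionless numbers
// of the model equations; time is on the dt grid (ms).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Spike-initiation exponent is capped at +20 before exponentiation so that
// transiently divergent untrained networks cannot overflow; the cap never
// binds for membrane potentials within ~10 mV of threshold.
static const double EXP_CAP = 20.0;

static inline vec safe_exp_arg(const vec& v, double v_th, double theta) {
  vec arg = (v - v_th) / theta;
  arg.transform([](double x) { return x > EXP_CAP ? EXP_CAP : x; });
  return arg;
}

// One forward pass over a [T x N_in] input matrix.  State convention:
// the trace row n holds the pre-reset membrane potential V(n), the
// adaptation A(n), synaptic current I(n) (which already contains u(n) and
// z(n-1)), the spike indicator Z(n) = H(V(n) - v_th) with H(0) = 1, and
// the readout Y(n) = kappa*Y(n-1) + W_out z(n-1) + b.
// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::mat& U,
                        const arma::mat& Win, const arma::mat& Wrec,
                        const arma::mat& Wout, const arma::vec& b,
                        double tau_m, double tau_a, double tau_s,
                        double v_th, double v_reset, double theta,
                        double a_s, double a_current,
                        double dt, double kappa,
                        const arma::vec& v0, const arma::vec& a0,
                        const arma::vec& I0, const arma::vec& y0,
                        const arma::vec& z0,
                        bool keep_trace = true) {
  const uword T = U.n_rows;
  const uword N = Wrec.n_rows;
  const uword Nout = Wout.n_rows;

  vec v = v0, a = a0, I = I0, y = y0, z_prev = z0;

  mat V, A, Im, Z, Y;
  if (keep_trace) {
    V.set_size(T, N); A.set_size(T, N); Im.set_size(T, N);
    Z.set_size(T, N); Y.set_size(T, Nout);
  }

  const double cm = dt / tau_m, ca = dt / tau_a, cs = dt / tau_s;

  for (uword n = 0; n < T; ++n) {
    // reset rules applied to spiking neurons before the Euler update
    vec vhat = v, ahat = a;
    for (uword j = 0; j < N; ++j) {
      if (z_prev(j) > 0.5) { vhat(j) = v_reset; ahat(j) += a_s; }
    }
    vec ex = theta * exp(safe_exp_arg(vhat, v_th, theta));
    vec vn = vhat + cm * (-vhat + ex + I - ahat);
    vec an = ahat + ca * (a_current * vhat - ahat);
    vec In = I * (1.0 - cs) + Win * U.row(n).t() + Wrec * z_prev;
    vec yn = kappa * y + Wout * z_prev + b;

    if (!vn.is_finite()) {
      uword bad = 0;
      for (uword j = 0; j < N; ++j) if (!std::isfinite(vn(j))) { bad = j; break; }
      Rcpp::stop("numerical blow-up at step %d, neuron %d", (int)(n + 1), (int)(bad + 1));
    }

    vec zn(N);
    for (uword j = 0; j < N; ++j) zn(j) = (vn(j) >= v_th) ? 1.0 : 0.0;

    if (keep_trace) {
      V.row(n) = vn.t(); A.row(n) = an.t(); Im.row(n) = In.t();
      Z.row(n) = zn.t(); Y.row(n) = yn.t();
    }
    v = vn; a = an; I = In; y = yn; z_prev = zn;
  }

  return Rcpp::List::create(
    Rcpp::Named("V") = V, Rcpp::Named("A") = A, Rcpp::Named("I") = Im,
    Rcpp::Named("Z") = Z, Rcpp::Named("Y") = Y,
    Rcpp::Named("v") = v, Rcpp::Named("a") = a, Rcpp::Named("I_end") = I,
    Rcpp::Named("y") = y, Rcpp::Named("z") = z_prev);
}

// Loss and gradients for one padded batch.
// Inputs/targets/mask are cubes [T x dim x B].  The gradient implements the
// reverse-mode (adjoint) accumulation of the forward sensitivity recursions:
// per-neuron (V, a) sensitivity propagation with detached recurrent spike
// input, SuperSpike pseudo-derivative on the spike path, and the exact chain
// rule through the exponential-filter readout.
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(const arma::cube& U, const arma::cube& target,
                          const arma::cube& mask,
                          const arma::mat& Win, const arma::mat& Wrec,
                          const arma::mat& Wout, const arma::vec& b,
                          double tau_m, double tau_a, double tau_s,
                          double v_th, double v_reset, double theta,
                          double a_s, double a_current,
                          double dt, double kappa, double alpha,
                          double lambda, double f_th,
                          bool rate_reg, bool paper_denominator) {
  const uword T = U.n_rows;
  const uword B = U.n_slices;
  const uword N = Wrec.n_rows;
  const uword Nout = Wout.n_rows;
  const double cm = dt / tau_m, ca = dt / tau_a, cs = dt / tau_s;

  // ---- forward pass, all trials, traces kept for the backward sweep ----
  cube V(T, N, B), Z(T, N, B), Y(T, Nout, B);
  vec spike_sum(N, fill::zeros);

  for (uword bt = 0; bt < B; ++bt) {
    vec v(N, fill::zeros), a(N, fill::zeros), I(N, fill::zeros);
    vec y(Nout, fill::zeros), z_prev(N, fill::zeros);
    const mat& Ub = U.slice(bt);
    for (uword n = 0; n < T; ++n) {
      vec vhat = v, ahat = a;
      for (uword j = 0; j < N; ++j)
        if (z_prev(j) > 0.5) { vhat(j) = v_reset; ahat(j) += a_s; }
      vec ex = theta * exp(safe_exp_arg(vhat, v_th, theta));
      vec vn = vhat + cm * (-vhat + ex + I - ahat);
      if (!vn.is_finite())
        Rcpp::stop("numerical blow-up at step %d (trial %d)", (int)(n + 1), (int)(bt + 1));
      vec an = ahat + ca * (a_current * vhat - ahat);
      vec In = I * (1.0 - cs) + Win * Ub.row(n).t() + Wrec * z_prev;
      vec yn = kappa * y + Wout * z_prev + b;
      vec zn(N);
      for (uword j = 0; j < N; ++j) zn(j) = (vn(j) >= v_th) ? 1.0 : 0.0;
      V.slice(bt).row(n) = vn.t();
      Z.slice(bt).row(n) = zn.t();
      Y.slice(bt).row(n) = yn.t();
      v = vn; a = an; I = In; y = yn; z_prev = zn;
      spike_sum += zn;
    }
  }

  // ---- loss ----
  double mask_sum = accu(mask);
  if (mask_sum <= 0.0) Rcpp::stop("undefined loss: mask sums to zero");
  double denom = paper_denominator
    ? (double)Nout * (double)B * (double)T * mask_sum
    : mask_sum;

  double sq = 0.0;
  for (uword bt = 0; bt < B; ++bt) {
    mat d = Y.slice(bt) - target.slice(bt);
    sq += accu(mask.slice(bt) % d % d);
  }
  double mse = sq / denom;

  // mean firing rates in Hz over batch and (padded) trial time
  vec f_hz = spike_sum * (1000.0 / dt) / ((double)B * (double)T);
  double er = 0.0;
  vec reg_sig(N, fill::zeros);
  if (rate_reg) {
    for (uword j = 0; j < N; ++j) {
      if (f_hz(j) >= f_th) {   // H(0) = 1 convention
        er += f_hz(j);
        // d f_j / d z_j(n,b), H treated as locally constant
        reg_sig(j) = lambda * (1000.0 / dt) / ((double)B * (double)T);
      }
    }
  }
  double loss = mse + (rate_reg ? lambda * er : 0.0);

  // ---- backward pass ----
  mat dWin(N, Win.n_cols, fill::zeros), dWrec(N, N, fill::zeros);
  mat dWout(Nout, N, fill::zeros);
  vec db(Nout, fill::zeros);

  for (uword bt = 0; bt < B; ++bt) {
    const mat& Ub = U.slice(bt);
    const mat& Vb = V.slice(bt);
    const mat& Zb = Z.slice(bt);
    mat q = 2.0 * (mask.slice(bt) % (Y.slice(bt) - target.slice(bt))) / denom;

    // readout adjoint r(n) = q(n) + kappa * r(n+1)
    mat r(T, Nout, fill::zeros);
    rowvec rn(Nout, fill::zeros);
    for (uword n = T; n-- > 0; ) {
      rn = q.row(n) + kappa * rn;
      r.row(n) = rn;
    }

    // learning signal at each step: surrogate derivative times the loss
    // sensitivity of z(n) (readout path uses r(n+1); z(T) feeds nothing
    // downstream through the readout)
    mat Lm(T, N, fill::zeros);
    if (T > 1) Lm.rows(0, T - 2) = r.rows(1, T - 1) * Wout;
    Lm.each_row() += reg_sig.t();
    mat sg = 1.0 / square(1.0 + abs(alpha * (Vb - v_th)));
    Lm %= sg;

    // Jacobian factor of the printed V-recursion, evaluated at the stored
    // (pre-reset) membrane potential, exponent capped as in the forward pass
    mat Jm = 1.0 + cm * (exp(clamp((Vb - v_th) / theta,
                                   -datum::inf, EXP_CAP)) - 1.0);

    // sensitivity adjoint over the per-neuron (V, a) recursions
    mat SV(T, N);
    vec sv(N, fill::zeros), sa(N, fill::zeros);
    for (uword n = T; n-- > 0; ) {
      vec sv_new = Lm.row(n).t() + Jm.row(n).t() % sv +
        (ca * a_current) * sa;
      vec sa_new = (1.0 - ca) * sa - cm * sv;
      sv = sv_new; sa = sa_new;
      SV.row(n) = sv.t();
    }

    // drives entering the sensitivity at step n:
    //   recurrent: z_k(n-1);  input: u_k(n)   (as printed)
    if (T > 1) dWrec += cm * (SV.rows(1, T - 1).t() * Zb.rows(0, T - 2));
    dWin += cm * (SV.t() * Ub);

    // readout weights: exact chain rule through y(n) = ... + Wout z(n-1)
    if (T > 1) dWout += r.rows(1, T - 1).t() * Zb.rows(0, T - 2);
    db += sum(r, 0).t();
  }
  dWrec.diag().zeros();

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("mse") = mse,
    Rcpp::Named("e_r") = er,
    Rcpp::Named("dW_in") = dWin, Rcpp::Named("dW_rec") = dWrec,
    Rcpp::Named("dW_out") = dWout, Rcpp::Named("db") = db,
    Rcpp::Named("rates_hz") = f_hz);
}
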