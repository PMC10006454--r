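#' AdEx neuron parameters
#'
#' Defaults are the parameter set used throughout: membrane time constant
#' `tau_m` = 10 ms, adaptation time `tau_a` = 2000 ms (2 s), synaptic time
#' `tau_s` = 5 ms, spike threshold `v_th` = 0.65 mV (0.45 mV when
#' `N = 256`), reset `v_reset` = 0 mV, spike-initiation sharpness `theta` =
#' 0.5 mV, adaptation jump `a_s` = 0.02, adaptation coupling `a_current` =
#' 4.  All quantities enter the discrete dynamics as the dimensionless
#' numbers printed here.
#'
#' @param N Network size (only used to pick the `v_th` default).
#' @param tau_m,tau_a,tau_s Time constants, ms.
#' @param v_th,v_reset,theta Threshold, reset and sharpness, mV.
#' @param a_s Adaptation increment applied at each spike.
#' @param a_current Adaptation coupling coefficient.
#' @return A `spikecog_neuron_params` list.
#' @export
neuron_params <- function(N = NULL, tau_m = 10, tau_a = 2000, tau_s = 5,
                          v_th = NULL, v_reset = 0, theta = 0.5,
                          a_s = 0.02, a_current = 4) {
  if (is.null(v_th))
    v_th <- if (!is.null(N) && N == 256) 0.45 else 0.65
  stopifnot(tau_m > 0, tau_a > 0, tau_s > 0, theta > 0)
  structure(list(tau_m = tau_m, tau_a = tau_a, tau_s = tau_s,
                 v_th = v_th, v_reset = v_reset, theta = theta,
                 a_s = a_s, a_current = a_current),
            class = "spikecog_neuron_params")
}

#' Initialize network weights
#'
#' Recurrent and input weights are drawn from `sqrt(2/N) * N(0, 1)`; the
#' diagonal of the recurrent matrix is zeroed (and is kept at zero by every
#' weight-writing operation, preventing neural self-excitation).  Readout
#' weights and biases are drawn from `U(-sqrt(1/N), sqrt(1/N))`.
#'
#' @param N Number of recurrent neurons.
#' @param N_in Number of input channels (fixation + 2 sensory + 12 task
#'   units = 15 for the full battery).
#' @param N_out Number of outputs (fixation + 2 response units).
#' @return A `spikecog_weights` list with `W_in` `[N x N_in]`, `W_rec`
#'   `[N x N]` (zero diagonal), `W_out` `[N_out x N]`, `b` `[N_out]`.
#' @export
#' @examples
#' set.seed(1)
#' w <- init_weights(64)
#' all(diag(w$W_rec) == 0)
init_weights <- function(N, N_in = 15, N_out = 3) {
  stopifnot(N >= 1, N_in >= 1, N_out >= 1)
  sd0 <- sqrt(2 / N)
  W_rec <- matrix(sd0 * rnorm(N * N), N, N)
  diag(W_rec) <- 0
  W_in <- matrix(sd0 * rnorm(N * N_in), N, N_in)
  lim <- sqrt(1 / N)
  W_out <- matrix(runif(N_out * N, -lim, lim), N_out, N)
  b <- runif(N_out, -lim, lim)
  structure(list(W_in = W_in, W_rec = W_rec, W_out = W_out, b = b),
            class = "spikecog_weights")
}

#' Fresh (or custom) per-step network state
#'
#' @param N Network size.
#' @param N_out Number of outputs.
#' @param v,a,I,y,z Optional initial values (default all zero).
#' @return A `spikecog_state` list.
#' @export
network_state <- function(N, N_out = 3, v = NULL, a = NULL, I = NULL,
                          y = NULL, z = NULL) {
  zeros <- function(x, n) if (is.null(x)) numeric(n) else x
  structure(list(v = zeros(v, N), a = zeros(a, N), I = zeros(I, N),
                 y = zeros(y, N_out), z = zeros(z, N)),
            class = "spikecog_state")
}

#' One Euler step of the discrete AdEx network (reference implementation)
#'
#' Takes the state at step `n` together with the input `u(n+1)` and returns
#' the state at step `n+1`.  Order of operations: the spike indicator
#' `z(n) = H(v(n) - v_th)` (with `H(0) = 1`) was evaluated from the
#' pre-reset membrane potential when the state was formed; spiking neurons
#' are reset (`v -> v_reset`, `a -> a + a_s`); the Euler update then advances
#' `v` and `a` from the post-reset values using the current `I(n)`, and the
#' synaptic current advances to
#' `I(n+1) = I(n) (1 - dt/tau_s) + W_in u(n+1) + W_rec z(n)`.
#' The readout advances as `y(n+1) = kappa y(n) + W_out z(n) + b`.
#'
#' This plain-R step is the reference used in tests; [simulate_trial()] runs
#' the same recurrence in compiled code.
#'
#' @param state A `spikecog_state` holding `(v, a, I, y, z)` at step n.
#' @param u_next Input vector `u(n+1)` of length `N_in`.
#' @param w A `spikecog_weights`.
#' @param p A `spikecog_neuron_params`.
#' @param dt Time step, ms.
#' @param kappa Readout filter parameter `exp(-dt/tau_out)`.
#' @return The `spikecog_state` at step n+1 (its `z` is evaluated from the
#'   new pre-reset membrane potential).
#' @export
adex_step <- function(state, u_next, w, p, dt = 1, kappa = exp(-1 / 2)) {
  # spike indicator re-derived from the pre-reset membrane potential so the
  # state invariant z = H(v - v_th) holds regardless of how `state` was built
  z_n <- as.numeric(state$v >= p$v_th)
  state$z <- z_n
  spiked <- z_n > 0.5
  vhat <- ifelse(spiked, p$v_reset, state$v)
  ahat <- state$a + p$a_s * spiked
  arg <- pmin((vhat - p$v_th) / p$theta, 20)
  v_new <- vhat + (dt / p$tau_m) *
    (-vhat + p$theta * exp(arg) + state$I - ahat)
  if (any(!is.finite(v_new)))
    stop("numerical blow-up in neuron ", which(!is.finite(v_new))[1])
  a_new <- ahat + (dt / p$tau_a) * (p$a_current * vhat - ahat)
  I_new <- state$I * (1 - dt / p$tau_s) +
    drop(w$W_in %*% u_next) + drop(w$W_rec %*% state$z)
  y_new <- readout_step(state$y, state$z, w, kappa)
  network_state(length(v_new), length(y_new),
                v = v_new, a = a_new, I = I_new, y = y_new,
                z = as.numeric(v_new >= p$v_th))
}

#' One step of the exponential-filter readout
#'
#' `y(n+1) = kappa * y(n) + W_out z(n) + b` with
#' `kappa = exp(-dt/tau_out)`.
#'
#' @param y Output vector at step n.
#' @param z Spike vector at step n.
#' @param w A `spikecog_weights`.
#' @param kappa Filter parameter, in (0, 1).
#' @return Output vector at step n+1.
#' @export
readout_step <- function(y, z, w, kappa) {
  stopifnot(kappa > 0, kappa < 1)
  kappa * y + drop(w$W_out %*% z) + w$b
}

#' Simulate the network over one trial
#'
#' Runs the discrete AdEx recurrence and the exponential-filter readout over
#' a rendered trial (or any `[N_step x N_in]` input matrix) in compiled
#' code.  Row `n` of the returned traces holds the pre-reset membrane
#' potentials `V(n)`, adaptation `A(n)`, synaptic currents `I(n)`, spike
#' indicators `Z(n)` and outputs `Y(n)`.  The run is deterministic given the
#' inputs and initial state; by default the trial starts from the zero state
#' but a final state from a previous trial can be chained in.
#'
#' @param w A `spikecog_weights`.
#' @param trial A `spikecog_trial` or a numeric input matrix
#'   `[N_step x N_in]`.
#' @param p A `spikecog_neuron_params`.
#' @param kappa Readout filter parameter.
#' @param dt Time step, ms.
#' @param init Optional `spikecog_state` to start from (for chaining
#'   trials); default zero state.
#' @return A `spikecog_trace` list with matrices `V`, `A`, `I`, `Z`
#'   `[N_step x N]`, `Y` `[N_step x N_out]`, and `final` (the end-of-trial
#'   `spikecog_state`).
#' @export
simulate_trial <- function(w, trial, p = neuron_params(nrow(w$W_rec)),
                           kappa = exp(-1 / 2), dt = 1, init = NULL) {
  U <- if (inherits(trial, "spikecog_trial")) trial$inputs else trial
  U <- as.matrix(U)
  N <- nrow(w$W_rec)
  N_out <- nrow(w$W_out)
  stopifnot(ncol(U) == ncol(w$W_in))
  if (is.null(init)) init <- network_state(N, N_out)
  if (nrow(U) == 0L) {
    return(structure(list(V = matrix(0, 0, N), A = matrix(0, 0, N),
                          I = matrix(0, 0, N), Z = matrix(0, 0, N),
                          Y = matrix(0, 0, N_out), final = init),
                     class = "spikecog_trace"))
  }
  res <- cpp_simulate(U, w$W_in, w$W_rec, w$W_out, w$b,
                      p$tau_m, p$tau_a, p$tau_s, p$v_th, p$v_reset,
                      p$theta, p$a_s, p$a_current, dt, kappa,
                      init$v, init$a, init$I, init$y, init$z, TRUE)
  structure(list(V = res$V, A = res$A, I = res$I, Z = res$Z, Y = res$Y,
                 final = network_state(N, N_out, v = drop(res$v),
                                       a = drop(res$a), I = drop(res$I_end),
                                       y = drop(res$y), z = drop(res$z))),
            class = "spikecog_trace")
}
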