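test_that("weight initialization follows the stated distributions", {
  set.seed(42)
  w <- init_weights(256)
  off <- w$W_rec[row(w$W_rec) != col(w$W_rec)]
  expect_lt(abs(sd(off) - sqrt(2 / 256)), 0.05 * sqrt(2 / 256))
  expect_lt(abs(mean(off)), 3 * sqrt(2 / 256) / sqrt(length(off)))
  expect_true(all(diag(w$W_rec) == 0))
  lim <- sqrt(1 / 256)
  expect_true(all(abs(w$W_out) <= lim) && all(abs(w$b) <= lim))
  expect_lt(abs(sd(w$W_in) - sqrt(2 / 256)), 0.1 * sqrt(2 / 256))
  # degenerate size
  expect_equal(init_weights(1)$W_rec, matrix(0, 1, 1))
})

test_that("a single Euler step reproduces the hand-derived update", {
  p <- neuron_params(2)
  w <- structure(list(W_in = matrix(0, 2, 15), W_rec = matrix(0, 2, 2),
                      W_out = matrix(0, 3, 2), b = rep(0, 3)),
                 class = "spikecog_weights")
  s1 <- adex_step(network_state(2), rep(0, 15), w, p)
  expect_equal(s1$v, rep(0.1 * 0.5 * exp(-1.3), 2), tolerance = 1e-12)
  # threshold is inclusive: v = v_th spikes (H(0) = 1) and resets
  s <- network_state(2, v = c(p$v_th, 0))
  s2 <- adex_step(s, rep(0, 15), w, p)
  expect_equal(s2$z, c(0, 0))          # z of the *new* state, from new v
  # the spiking neuron was reset to v_reset, a incremented by a_s, before
  # the Euler update
  expect_equal(s2$v[1], 0.1 * (0.5 * exp(-1.3) - p$a_s), tolerance = 1e-12)
  expect_equal(s2$v[2], 0.1 * 0.5 * exp(-1.3), tolerance = 1e-12)
  expect_equal(s2$a[1], p$a_s * (1 - 1 / p$tau_a), tolerance = 1e-12)
})

test_that("synaptic current decays geometrically without input or spikes", {
  p <- neuron_params(1)
  w <- structure(list(W_in = matrix(0, 1, 15), W_rec = matrix(0, 1, 1),
                      W_out = matrix(0, 3, 1), b = rep(0, 3)),
                 class = "spikecog_weights")
  s <- network_state(1, I = 2)
  for (n in 1:5) {
    s <- adex_step(s, rep(0, 15), w, p)
    expect_equal(s$I, 2 * (1 - 1 / p$tau_s)^n, tolerance = 1e-12)
  }
})

test_that("readout follows the exponential filter exactly", {
  set.seed(8)
  w <- init_weights(6)
  kappa <- exp(-1 / 50)
  # homogeneous decay
  y <- c(1, -2, 0.5)
  w0 <- w; w0$W_out[] <- 0; w0$b[] <- 0
  for (n in 1:10) y <- readout_step(y, numeric(6), w0, kappa)
  expect_equal(y, kappa^10 * c(1, -2, 0.5), tolerance = 1e-12)
  # affine fixed point b / (1 - kappa)
  wb <- w0; wb$b <- c(0.1, 0.2, -0.3)
  y <- numeric(3)
  for (n in 1:5000) y <- readout_step(y, numeric(6), wb, kappa)
  expect_equal(y, wb$b / (1 - kappa), tolerance = 1e-8)
  # brute-force convolution on a random 50-step spike train
  Z <- matrix(rbinom(50 * 6, 1, 0.3), 50, 6)
  y <- numeric(3)
  for (n in 1:50) y <- readout_step(y, Z[n, ], w, kappa)
  conv <- rowSums(sapply(1:50, function(k)
    kappa^(50 - k) * (w$W_out %*% Z[k, ] + w$b)))
  expect_equal(y, drop(conv), tolerance = 1e-12)
})

test_that("compiled simulation matches the plain-R step loop", {
  set.seed(9)
  w <- random_small_net(5, seed = 9, gain = 3)
  p <- neuron_params(5); p$v_th <- 0.3
  U <- matrix(rnorm(40 * 15, 0, 0.5), 40, 15)
  tr <- simulate_trial(w, U, p, kappa = exp(-1 / 2))
  s <- network_state(5)
  for (n in 1:40) {
    s <- adex_step(s, U[n, ], w, p, dt = 1, kappa = exp(-1 / 2))
    expect_equal(s$v, tr$V[n, ], tolerance = 1e-12)
    expect_equal(as.numeric(s$v >= p$v_th), tr$Z[n, ])
    expect_equal(s$y, tr$Y[n, ], tolerance = 1e-12)
  }
  expect_gt(sum(tr$Z), 0)            # the comparison covered real spikes
})

test_that("quiescent network stays subthreshold under zero input", {
  w <- structure(list(W_in = matrix(0, 3, 15), W_rec = matrix(0, 3, 3),
                      W_out = matrix(0, 3, 3), b = rep(0, 3)),
                 class = "spikecog_weights")
  tr <- simulate_trial(w, matrix(0, 2000, 15), neuron_params(3))
  expect_equal(sum(tr$Z), 0)
  # v drifts toward the subthreshold equilibrium of the coupled (v, a)
  # dynamics, 5 v* = theta exp((v* - v_th)/theta), and stays below threshold
  vstar <- tr$V[2000, 1]
  expect_lt(vstar, 0.65)
  expect_gt(vstar, 0)
  vroot <- uniroot(function(v) 5 * v - 0.5 * exp((v - 0.65) / 0.5),
                   c(0, 0.65))$root
  expect_equal(vstar, vroot, tolerance = 0.05)
})

test_that("empty input gives an empty trace", {
  w <- init_weights(3)
  tr <- simulate_trial(w, matrix(0, 0, 15))
  expect_identical(nrow(tr$Y), 0L)
})

test_that("adaptation stays zero without coupling, spikes or initial value", {
  p <- neuron_params(2); p$a_current <- 0
  w <- structure(list(W_in = matrix(0, 2, 15), W_rec = matrix(0, 2, 2),
                      W_out = matrix(0, 3, 2), b = rep(0, 3)),
                 class = "spikecog_weights")
  tr <- simulate_trial(w, matrix(0, 500, 15), p)
  expect_true(all(tr$A == 0))
})

test_that("single-neuron adaptation dynamics match the continuous account", {
  # sustained suprathreshold pulse: firing slows and stops as the adaptation
  # variable accumulates, then resumes after an input gap
  p <- neuron_params(1)
  w <- structure(list(W_in = matrix(c(1, rep(0, 14)), 1, 15),
                      W_rec = matrix(0, 1, 1), W_out = matrix(0, 3, 1),
                      b = rep(0, 3)),
                 class = "spikecog_weights")
  inject <- function(I0, n, dt = 1)
    cbind(rep(I0 * dt / p$tau_s, n), matrix(0, n, 14))
  U <- rbind(inject(0.5, 4000), inject(0, 2000), inject(0.5, 2000))
  tr <- simulate_trial(w, U, p)
  st <- which(tr$Z[, 1] == 1)
  in_pulse <- st[st <= 4000]
  expect_gt(length(in_pulse), 3)
  expect_lt(max(in_pulse), 4000)                  # ceases before offset
  expect_true(all(diff(diff(in_pulse)) > 0))      # ISIs strictly increase
  expect_gt(length(st[st > 6000]), 0)             # resumes after the gap
  # adaptation variable rises during the pulse and decays during the gap
  expect_gt(tr$A[4000, 1], tr$A[1, 1])
  expect_lt(tr$A[6000, 1], tr$A[4000, 1])
})

test_that("spike counts are consistent under Euler step refinement", {
  p <- neuron_params(1)
  w <- structure(list(W_in = matrix(c(1, rep(0, 14)), 1, 15),
                      W_rec = matrix(0, 1, 1), W_out = matrix(0, 3, 1),
                      b = rep(0, 3)),
                 class = "spikecog_weights")
  counts <- sapply(c(1, 0.1), function(dt) {
    n <- as.integer(4000 / dt)
    U <- cbind(rep(0.5 * dt / p$tau_s, n), matrix(0, n, 14))
    sum(simulate_trial(w, U, p, dt = dt)$Z)
  })
  expect_lte(abs(diff(counts)), 2)
})

test_that("trial chaining carries the final state over", {
  set.seed(4)
  w <- random_small_net(4, seed = 4, gain = 2)
  p <- neuron_params(4)
  U <- matrix(rnorm(60 * 15, 0, 0.3), 60, 15)
  whole <- simulate_trial(w, U, p)
  first <- simulate_trial(w, U[1:30, ], p)
  second <- simulate_trial(w, U[31:60, ], p, init = first$final)
  expect_equal(second$V, whole$V[31:60, ], tolerance = 1e-12)
  expect_equal(second$Y, whole$Y[31:60, ], tolerance = 1e-12)
})
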