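test_that("masked MSE matches the printed formula", {
  expect_identical(masked_mse(c(0.5, 0), c(0, 1), c(1, 5)), 0.4375)
  expect_identical(masked_mse(c(1, 1), c(1, 1), c(1, 5)), 0)
  # doubling the mask leaves the loss unchanged (numerator and denominator)
  set.seed(1)
  y <- matrix(runif(30), 10, 3); t0 <- matrix(runif(30), 10, 3)
  m <- matrix(sample(c(1, 5), 30, TRUE), 10, 3)
  expect_equal(masked_mse(y, t0, m), masked_mse(y, t0, 2 * m))
  expect_equal(masked_mse(y, t0, m, "mask_sum"),
               masked_mse(y, t0, 2 * m, "mask_sum"))
  # the two denominator conventions differ by the constant N_out*N_batch*N_step
  expect_equal(masked_mse(y, t0, m, "mask_sum"),
               masked_mse(y, t0, m, "paper") * 3 * 1 * 10)
  expect_error(masked_mse(y, t0, 0 * m), "mask sums to zero")
})

test_that("rate regularizer sums rates at or above threshold", {
  expect_identical(rate_regularizer(rates_hz = c(10, 40, 50), f_th = 30), 90)
  expect_identical(rate_regularizer(rates_hz = c(10, 20), f_th = 30), 0)
  # H(0) = 1: the threshold itself is penalized
  expect_identical(rate_regularizer(rates_hz = c(30, 10), f_th = 30), 30)
  expect_identical(rate_regularizer(rates_hz = c(3, 7), f_th = 0), 10)
  # from a spike matrix: 2 of 4 steps spiking at dt = 1 ms -> 500 Hz
  Z <- matrix(c(1, 0, 1, 0), 4, 1)
  expect_equal(rate_regularizer(Z, f_th = 30, dt = 1), 500)
})

test_that("SuperSpike surrogate has the printed form and shape", {
  expect_identical(surrogate_derivative(0.65, 0.65), 1)
  expect_equal(surrogate_derivative(0.66, 0.65, 100), 0.25)
  v <- seq(-0.2, 0.2, by = 0.01)
  s <- surrogate_derivative(0.65 + v, 0.65)
  expect_equal(s, rev(s))                       # even in v - v_th
  expect_true(all(diff(s[v >= 0]) < 0))         # decreasing in |v - v_th|
})

test_that("forward sensitivities equal the reverse-mode oracle", {
  # random instances up to N = 4, T = 30, both loss variants
  cases <- list(
    list(N = 2, T_stim = 12, T_resp = 8, variant = "mse", seed = 21),
    list(N = 4, T_stim = 20, T_resp = 10, variant = "mse", seed = 22),
    list(N = 3, T_stim = 15, T_resp = 10, variant = "mse_plus_rate_reg",
         seed = 23))
  for (cs in cases) {
    set.seed(cs$seed)
    w <- random_small_net(cs$N, seed = cs$seed, gain = 3)
    p <- neuron_params(cs$N); p$v_th <- 0.3
    cfg <- train_config(loss_variant = cs$variant, n_epoch = 1, n_batch = 2)
    trials <- list(
      render_trial(manual_spec("DM1", cs$T_stim, T_resp = cs$T_resp,
                               a = 0.8)),
      render_trial(manual_spec("Go2", cs$T_stim - 4, T_resp = cs$T_resp,
                               a = 4 / 7)))
    batch <- assemble_batch(trials, cfg$mask_values)
    got <- forward_sensitivities(batch, w, p, cfg)
    want <- bptt_oracle(batch, w, p, cfg)
    denom <- function(x) max(max(abs(x)), 1e-300)
    for (nm in c("dW_in", "dW_rec", "dW_out", "db")) {
      expect_lt(max(abs(got[[nm]] - want[[nm]])) / denom(want[[nm]]), 1e-6)
    }
    expect_true(all(diag(got$dW_rec) == 0))
  }
})

test_that("compiled batch gradients equal the forward sensitivities", {
  set.seed(31)
  w <- random_small_net(4, seed = 31, gain = 3)
  p <- neuron_params(4); p$v_th <- 0.3
  for (variant in c("mse", "mse_plus_rate_reg")) {
    cfg <- train_config(loss_variant = variant, n_epoch = 1, n_batch = 2)
    batch <- assemble_batch(list(
      render_trial(manual_spec("DM1", 20, a = 0.8)),
      render_trial(manual_spec("Romo1", 6, T_delay = 6, a = c(0.9, 0.2)))),
      cfg$mask_values)
    g_r <- forward_sensitivities(batch, w, p, cfg)
    pc <- function(a) aperm(a, c(1, 3, 2))
    g_c <- spikecog:::cpp_batch_grad(
      pc(batch$inputs), pc(batch$targets), pc(batch$mask),
      w$W_in, w$W_rec, w$W_out, w$b, p$tau_m, p$tau_a, p$tau_s, p$v_th,
      p$v_reset, p$theta, p$a_s, p$a_current, cfg$dt,
      exp(-cfg$dt / cfg$tau_out), cfg$alpha, cfg$lambda_reg, cfg$f_th,
      variant == "mse_plus_rate_reg", cfg$denominator == "paper")
    expect_equal(g_r$loss, g_c$loss, tolerance = 1e-12)
    for (nm in c("dW_in", "dW_rec", "dW_out"))
      expect_equal(g_r[[nm]], g_c[[nm]], tolerance = 1e-10)
    expect_equal(g_r$db, drop(g_c$db), tolerance = 1e-10)
  }
})

test_that("readout gradients match central finite differences", {
  # W_out and b do not influence the spiking dynamics, so their analytic
  # gradient must match finite differences even on trials with spikes
  set.seed(41)
  w <- random_small_net(3, seed = 41, gain = 3)
  p <- neuron_params(3); p$v_th <- 0.3
  cfg <- train_config(loss_variant = "mse", n_epoch = 1, n_batch = 1)
  batch <- assemble_batch(list(render_trial(manual_spec("DM1", 15, a = 0.8))),
                          cfg$mask_values)
  g <- forward_sensitivities(batch, w, p, cfg)
  lossfun <- function(ww) forward_sensitivities(batch, ww, p, cfg)$loss
  h <- 1e-5
  for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
    wp <- w; wp$W_out[idx[1], idx[2]] <- wp$W_out[idx[1], idx[2]] + h
    wm <- w; wm$W_out[idx[1], idx[2]] <- wm$W_out[idx[1], idx[2]] - h
    fd <- (lossfun(wp) - lossfun(wm)) / (2 * h)
    expect_equal(g$dW_out[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
  wp <- w; wp$b[2] <- wp$b[2] + h
  wm <- w; wm$b[2] <- wm$b[2] - h
  expect_equal(g$db[2], (lossfun(wp) - lossfun(wm)) / (2 * h),
               tolerance = 1e-4)
})

test_that("loss decomposes exactly and lambda = 0 recovers pure MSE", {
  set.seed(51)
  w <- random_small_net(4, seed = 51, gain = 3)
  p <- neuron_params(4); p$v_th <- 0.3
  cfg_reg <- train_config("mse_plus_rate_reg", lambda_reg = 0.7,
                          n_batch = 1)
  batch <- assemble_batch(list(render_trial(manual_spec("DM1", 20, a = 0.8))),
                          cfg_reg$mask_values)
  g <- forward_sensitivities(batch, w, p, cfg_reg)
  expect_identical(g$loss, g$mse + 0.7 * g$e_r)
  # lambda = 0: gradients identical to the mse-only variant bit-for-bit
  cfg0 <- cfg_reg; cfg0$lambda_reg <- 0
  cfg_mse <- cfg_reg; cfg_mse$loss_variant <- "mse"
  g0 <- forward_sensitivities(batch, w, p, cfg0)
  gm <- forward_sensitivities(batch, w, p, cfg_mse)
  for (nm in c("dW_in", "dW_rec", "dW_out", "db", "loss"))
    expect_identical(g0[[nm]], gm[[nm]])
})

test_that("weight updates implement SGD and Adam with the zero-diagonal
           invariant", {
  set.seed(61)
  w <- init_weights(4)
  cfg <- train_config(optimizer = "sgd", eta = 0.1, n_batch = 1)
  g <- list(dW_in = matrix(1, 4, 15), dW_rec = diag(4) + 1,
            dW_out = matrix(2, 3, 4), db = c(1, 2, 3))
  upd <- apply_update(w, g, optimizer_state(w), cfg)
  expect_equal(upd$weights$W_in, w$W_in - 0.1, ignore_attr = TRUE)
  expect_equal(upd$weights$b, w$b - 0.1 * c(1, 2, 3))
  # diagonal gradient entries are discarded; diagonal stays zero
  expect_true(all(diag(upd$weights$W_rec) == 0))
  off <- row(w$W_rec) != col(w$W_rec)
  expect_equal(upd$weights$W_rec[off], w$W_rec[off] - 0.1 * 1)
  # non-finite gradients abort
  gbad <- g; gbad$dW_in[1] <- NaN
  expect_error(apply_update(w, gbad, optimizer_state(w), cfg),
               "non-finite gradient")
  # Adam with a constant gradient: per-step update magnitude tends to eta
  cfg_a <- train_config(optimizer = "adam", eta = 0.01, n_batch = 1)
  wa <- w; opt <- optimizer_state(wa)
  gc <- list(dW_in = matrix(0.3, 4, 15), dW_rec = matrix(0, 4, 4),
             dW_out = matrix(0.3, 3, 4), db = rep(0.3, 3))
  prev <- wa$b[1]
  for (i in 1:200) {
    res <- apply_update(wa, gc, opt, cfg_a)
    wa <- res$weights; opt <- res$opt
  }
  last <- wa$b[1]
  res <- apply_update(wa, gc, opt, cfg_a)
  expect_equal(abs(res$weights$b[1] - last), 0.01, tolerance = 1e-3)
})

test_that("training is deterministic and decreases the loss in trend", {
  cfg <- train_config(loss_variant = "mse", n_epoch = 40, n_batch = 4,
                      eta = 5e-3, denominator = "mask_sum", seed = 5,
                      T_stim_range = c(100, 200))
  set.seed(99); w0 <- init_weights(32)
  r1 <- train(w0, cfg, tasks = c("DM1", "Go1"), p = neuron_params(32))
  r2 <- train(w0, cfg, tasks = c("DM1", "Go1"), p = neuron_params(32))
  expect_identical(r1$weights, r2$weights)        # same seed, same run
  expect_identical(r1$history$loss, r2$history$loss)
  expect_lt(mean(r1$history$loss[31:40]), mean(r1$history$loss[1:10]))
  expect_true(all(diag(r1$weights$W_rec) == 0))
  # eta = 0 leaves the weights unchanged but computes a finite loss
  cfg0 <- train_config(loss_variant = "mse", n_epoch = 1, n_batch = 2,
                       eta = 0, optimizer = "sgd", seed = 1,
                       T_stim_range = c(100, 150))
  r0 <- train(w0, cfg0, tasks = "DM1", p = neuron_params(32))
  expect_identical(r0$weights, w0)
  expect_true(is.finite(r0$history$loss[1]))
})
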