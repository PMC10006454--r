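# Independent oracles used across the suite.  These re-derive expected
# results from first principles (literal loops, exhaustive enumeration,
# closed forms) and never call the code paths they check.

# ---------------------------------------------------------------------------
# Reverse-mode backpropagation-through-time over the surrogate-gradient
# computational graph: per-neuron local sensitivities (recurrent spike
# inputs detached, reset jumps gradient-transparent), SuperSpike surrogate
# on the spike path, exact chain rule through the readout.  Written as a
# literal step-by-step backward sweep with scalar-level loops, independent
# of both forward_sensitivities() and the compiled trainer.
bptt_oracle <- function(batch, w, p, cfg) {
  dt <- cfg$dt
  kappa <- exp(-dt / cfg$tau_out)
  dims <- dim(batch$inputs)
  TT <- dims[1]; B <- dims[2]
  N <- nrow(w$W_rec); N_in <- ncol(w$W_in); N_out <- nrow(w$W_out)
  cm <- dt / p$tau_m; ca <- dt / p$tau_a
  use_reg <- cfg$loss_variant == "mse_plus_rate_reg"

  # own forward pass (plain R), storing pre-reset V, Z, Y
  fwd <- function(U) {
    v <- numeric(N); a <- numeric(N); I <- numeric(N)
    y <- numeric(N_out); z <- numeric(N)
    V <- matrix(0, TT, N); Z <- matrix(0, TT, N); Y <- matrix(0, TT, N_out)
    for (n in seq_len(TT)) {
      vh <- ifelse(z > 0.5, p$v_reset, v)
      ah <- a + p$a_s * (z > 0.5)
      vn <- vh + cm * (-vh + p$theta * exp(pmin((vh - p$v_th) / p$theta, 20))
                       + I - ah)
      an <- ah + ca * (p$a_current * vh - ah)
      In <- I * (1 - dt / p$tau_s) + drop(w$W_in %*% U[n, ]) +
        drop(w$W_rec %*% z)
      yn <- kappa * y + drop(w$W_out %*% z) + w$b
      zn <- as.numeric(vn >= p$v_th)
      V[n, ] <- vn; Z[n, ] <- zn; Y[n, ] <- yn
      v <- vn; a <- an; I <- In; y <- yn; z <- zn
    }
    list(V = V, Z = Z, Y = Y)
  }
  sims <- lapply(seq_len(B), function(b) fwd(batch$inputs[, b, , drop = TRUE]))

  msum <- sum(batch$mask)
  D <- if (cfg$denominator == "paper") N_out * B * TT * msum else msum
  f_hz <- Reduce(`+`, lapply(sims, function(s) colSums(s$Z))) *
    (1000 / dt) / (B * TT)
  reg_sig <- if (use_reg)
    cfg$lambda_reg * (f_hz >= cfg$f_th) * (1000 / dt) / (B * TT)
  else numeric(N)

  dW_in <- matrix(0, N, N_in); dW_rec <- matrix(0, N, N)
  dW_out <- matrix(0, N_out, N); db <- numeric(N_out)

  for (b in seq_len(B)) {
    s <- sims[[b]]
    U <- batch$inputs[, b, , drop = TRUE]
    gy <- 2 * (batch$mask[, b, , drop = TRUE] *
                 (s$Y - batch$targets[, b, , drop = TRUE])) / D
    # cumulative y-adjoint r(n) = dE/dy(n) including downstream filtering
    r <- matrix(0, TT, N_out)
    acc <- numeric(N_out)
    for (n in TT:1) { acc <- gy[n, ] + kappa * acc; r[n, ] <- acc }
    gv <- numeric(N); ga <- numeric(N)
    for (n in TT:1) {
      dz_n <- if (n < TT) drop(crossprod(w$W_out, r[n + 1, ]))
      else numeric(N)
      dz_n <- dz_n + reg_sig
      sgp <- (1 + abs(cfg$alpha * (s$V[n, ] - p$v_th)))^-2
      L <- sgp * dz_n
      Jn <- 1 + cm * (exp(pmin((s$V[n, ] - p$v_th) / p$theta, 20)) - 1)
      gv_new <- L + Jn * gv + ca * p$a_current * ga
      ga_new <- (1 - ca) * ga - cm * gv
      gv <- gv_new; ga <- ga_new
      zprev <- if (n == 1) numeric(N) else s$Z[n - 1, ]
      for (j in seq_len(N)) {
        dW_rec[j, ] <- dW_rec[j, ] + cm * gv[j] * zprev
        dW_in[j, ] <- dW_in[j, ] + cm * gv[j] * U[n, ]
      }
      dW_out <- dW_out + outer(r[n, ], zprev)
      db <- db + r[n, ]
    }
  }
  diag(dW_rec) <- 0
  list(dW_in = dW_in, dW_rec = dW_rec, dW_out = dW_out, db = db)
}

# ---------------------------------------------------------------------------
# Exhaustive k-means optimum: enumerate every assignment of n points to k
# labels and minimize the quadratic objective.  Feasible for n <= 8, k <= 3.
exhaustive_kmeans_J <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  assign_vec <- integer(n)
  recurse <- function(i) {
    if (i > n) {
      if (length(unique(assign_vec)) == k) {
        J <- 0
        for (cl in unique(assign_vec)) {
          pts <- x[assign_vec == cl, , drop = FALSE]
          mu <- colMeans(pts)
          J <- J + sum(sweep(pts, 2, mu)^2)
        }
        if (J < best) best <<- J
      }
      return(invisible())
    }
    for (lab in seq_len(k)) {
      assign_vec[i] <<- lab
      recurse(i + 1)
    }
  }
  recurse(1)
  best
}

# ---------------------------------------------------------------------------
# Brute-force Ward agglomeration: clusters merged by the minimal increase in
# within-cluster sum of squares, computed from scratch at every step.
brute_ward <- function(x) {
  x <- as.matrix(x)
  ess <- function(idx) {
    pts <- x[idx, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      R <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (R < best[1]) best <- c(R, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters <- c(clusters, list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a set partition for comparison
canonical_partition <- function(groups) {
  gs <- lapply(groups, sort)
  gs[order(vapply(gs, `[`, 1L, 1L))]
}

# partition of n items implied by an hclust at each merge step
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1), function(step) {
    labels <- stats::cutree(hc, k = n - step)
    unname(split(seq_len(n), labels))
  })
}

# ---------------------------------------------------------------------------
# small helpers for constructing fixed-timing trials without random draws
manual_spec <- function(task, T_stim, T_delay = 0, T_resp = 10, a = 0.7,
                        sigma = 0.05, dt = 1, u_th = 0.5) {
  id <- task_id(task)
  structure(list(task = task, family = id$family, modality = id$modality,
                 T_stim = T_stim, T_delay = T_delay, T_resp = T_resp,
                 a_stim = a, noise_sigma = sigma, dt = dt, u_th = u_th),
            class = "spikecog_trial_spec")
}

random_small_net <- function(N = 4, seed = 1, gain = 2) {
  set.seed(seed)
  w <- init_weights(N)
  w$W_in <- w$W_in * gain
  w$W_rec <- w$W_rec * gain
  diag(w$W_rec) <- 0
  w
}
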