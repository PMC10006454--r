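#' Build a neurons-by-time state matrix from simulation traces
#'
#' Concatenates the chosen dynamic variable (membrane potential `v` or
#' adaptation `a`) of a set of trials into an `N x N_times` matrix whose
#' column t holds all neurons' values at one moment.  The two variables are
#' analyzed separately because they evolve on very different time scales.
#'
#' @param traces Non-empty list of `spikecog_trace`s sharing the network
#'   size.
#' @param variable `"v"` or `"a"`.
#' @return A `spikecog_state_matrix`: `data` `[N x N_times]` (uncentered),
#'   `variable`, `boundaries` (cumulative trial end columns).
#' @export
build_state_matrix <- function(traces, variable = c("v", "a")) {
  variable <- match.arg(variable)
  if (length(traces) == 0L) stop("empty trace list")
  field <- if (variable == "v") "V" else "A"
  mats <- lapply(traces, function(tr) t(tr[[field]]))
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("traces have different network sizes")
  structure(list(data = do.call(cbind, mats), variable = variable,
                 boundaries = cumsum(vapply(mats, ncol, 1L))),
            class = "spikecog_state_matrix")
}

#' Principal component projection of population trajectories
#'
#' Row-centers the state matrix (per-neuron mean removal, no variance
#' scaling — the membrane and adaptation variables are kept apart precisely
#' because of their scale difference) and takes the top-k singular
#' directions of the neuron space.  Trajectories are returned per trial.
#'
#' @param m A `spikecog_state_matrix` (or plain `N x N_times` matrix).
#' @param k Number of components (default 3).
#' @return A `spikecog_pca`: `components` `[N x k]` (orthonormal loading
#'   vectors), `variance_ratio` (non-increasing, sums to <= 1),
#'   `trajectories` (list of `[k x T_i]` per-trial projections, one element
#'   when no boundaries are known), `center`.
#' @export
pca_project <- function(m, k = 3) {
  X <- if (inherits(m, "spikecog_state_matrix")) m$data else as.matrix(m)
  boundaries <- if (inherits(m, "spikecog_state_matrix")) m$boundaries
  else ncol(X)
  stopifnot(k >= 1)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  s <- svd(Xc)
  ev <- s$d^2
  rank <- sum(s$d > max(s$d[1], 1) * 1e-12 * max(dim(X)))
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; returning ", rank)
    k <- max(rank, 1L)
  }
  comps <- s$u[, seq_len(k), drop = FALSE]
  proj <- crossprod(comps, Xc)          # k x N_times
  starts <- c(1L, head(boundaries, -1L) + 1L)
  trajectories <- Map(function(s0, e0) proj[, s0:e0, drop = FALSE],
                      starts, boundaries)
  structure(list(components = comps,
                 variance_ratio = ev[seq_len(k)] / sum(ev),
                 trajectories = trajectories, center = ctr),
            class = "spikecog_pca")
}

#' Instantaneous firing rates by causal boxcar smoothing
#'
#' Converts a binary spike matrix into rates in Hz using a causal boxcar
#' window (spike count over the trailing `window` ms divided by the window
#' length), zero-padded before the trial start.
#'
#' @param Z Spike matrix `[N_step x N]` (or vector).
#' @param window Window length, ms (default 50).
#' @param dt Time step, ms.
#' @return Rate matrix of the same shape, Hz.
#' @export
smooth_rates <- function(Z, window = 50, dt = 1) {
  Z <- as.matrix(Z)
  wsteps <- max(1L, as.integer(round(window / dt)))
  cs <- apply(Z, 2, cumsum)
  cs <- rbind(matrix(0, 1, ncol(Z)), cs)
  n <- nrow(Z)
  lo <- pmax(seq_len(n) - wsteps, 0L)
  counts <- cs[seq_len(n) + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  counts / (wsteps * dt) * 1000
}

#' Demixed decomposition of a condition tensor
#'
#' Splits condition-averaged population activity `X[n, s, d, t]` (neurons x
#' stimuli x decisions x time) into additive marginals: a
#' condition-independent time component, a stimulus component (stimulus main
#' effect and stimulus-time interaction, averaged over decisions), a
#' decision component (likewise averaged over stimuli), and a residual
#' noise term (the stimulus-decision interaction).  The terms reconstruct
#' the input tensor exactly, and in a balanced design the stimulus and
#' decision marginals are mutually orthogonal.  Only the
#' marginalization-average decomposition is performed (no reduced-rank
#' regression or regularization); per-marginalization components come from
#' [dpca_components()].
#'
#' @param x Numeric 4-D array `[N x S x D x T]`.  A 5-D array with a
#'   trailing trial axis is averaged over trials first (the trial-to-trial
#'   variability then contributes to nothing here; pass the average of
#'   interest directly for exact reconstruction).
#' @return A `spikecog_dpca`: `mean` `[N]`, `X_t` `[N x T]`, `X_s`
#'   `[N x S x T]`, `X_d` `[N x D x T]`, `X_noise` `[N x S x D x T]`,
#'   `variance` (named vector of squared norms per marginalization over the
#'   full grid), `variance_ratio`.
#' @export
dpca_decompose <- function(x) {
  if (length(dim(x)) == 5L) x <- apply(x, 1:4, mean)
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  N <- d[1]; S <- d[2]; D <- d[3]; T_ <- d[4]
  if (S < 2 && D < 2)
    stop("need at least 2 stimulus levels or 2 decisions")
  if (S < 2) warning("singleton stimulus axis: stimulus marginal is zero")
  if (D < 2) warning("singleton decision axis: decision marginal is zero")

  m <- apply(x, 1, mean)                       # per-neuron grand mean
  mean_sd <- apply(x, c(1, 4), mean)           # [N x T]
  X_t <- mean_sd - m
  mean_d <- apply(x, c(1, 2, 4), mean)         # [N x S x T]
  mean_s <- apply(x, c(1, 3, 4), mean)         # [N x D x T]
  X_s <- mean_d
  for (s in seq_len(S)) X_s[, s, ] <- mean_d[, s, ] - mean_sd
  X_d <- mean_s
  for (dd in seq_len(D)) X_d[, dd, ] <- mean_s[, dd, ] - mean_sd
  X_noise <- x
  for (s in seq_len(S)) for (dd in seq_len(D))
    X_noise[, s, dd, ] <- x[, s, dd, ] - m - X_t - X_s[, s, ] - X_d[, dd, ]

  # squared norms over the full [N x S x D x T] grid (broadcast counts)
  variance <- c(time = sum(X_t^2) * S * D,
                stimulus = sum(X_s^2) * D,
                decision = sum(X_d^2) * S,
                noise = sum(X_noise^2))
  total <- sum(variance)
  structure(list(mean = m, X_t = X_t, X_s = X_s, X_d = X_d,
                 X_noise = X_noise, variance = variance,
                 variance_ratio = if (total > 0) variance / total
                 else variance),
            class = "spikecog_dpca")
}

#' Reconstruct the condition tensor from a demixed decomposition
#'
#' @param dec A `spikecog_dpca`.
#' @return The 4-D array `mean + X_t + X_s + X_d + X_noise` (exact additive
#'   reconstruction).
#' @export
dpca_reconstruct <- function(dec) {
  N <- length(dec$mean); S <- dim(dec$X_s)[2]; D <- dim(dec$X_d)[2]
  T_ <- ncol(dec$X_t)
  x <- array(0, c(N, S, D, T_))
  for (s in seq_len(S)) for (dd in seq_len(D))
    x[, s, dd, ] <- dec$mean + dec$X_t + dec$X_s[, s, ] + dec$X_d[, dd, ] +
      dec$X_noise[, s, dd, ]
  x
}

#' Demixed components of one marginalization
#'
#' PCA of a single marginal (its unfolded neurons-by-conditions matrix):
#' returns the top-k neuron-space axes of that marginalization and the
#' marginal's projection onto them — e.g. the "first stimulus demixed
#' component" time courses per stimulus level.
#'
#' @param dec A `spikecog_dpca`.
#' @param marginal `"time"`, `"stimulus"` or `"decision"`.
#' @param k Number of components.
#' @return List with `components` `[N x k]`, `scores` (for `"time"` a
#'   `[k x T]` matrix; otherwise a `[k x levels x T]` array),
#'   `variance_ratio` within the marginalization.
#' @export
dpca_components <- function(dec, marginal = c("time", "stimulus",
                                              "decision"), k = 1) {
  marginal <- match.arg(marginal)
  Xm <- switch(marginal, time = dec$X_t, stimulus = dec$X_s,
               decision = dec$X_d)
  dm <- dim(Xm)
  flat <- if (length(dm) == 3L) matrix(Xm, dm[1], dm[2] * dm[3]) else Xm
  s <- svd(flat)
  k <- min(k, sum(s$d > 1e-12 * max(s$d[1], 1)))
  k <- max(k, 1L)
  comps <- s$u[, seq_len(k), drop = FALSE]
  proj <- crossprod(comps, flat)
  scores <- if (length(dm) == 3L) array(proj, c(k, dm[2], dm[3])) else proj
  list(components = comps, scores = scores,
       variance_ratio = (s$d^2 / sum(s$d^2))[seq_len(k)])
}
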