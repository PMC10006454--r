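#' Score one simulated trial
#'
#' Applies the accuracy protocol: the trial fails outright unless the
#' fixation output criterion holds (by default, the mean of `y_fix` over the
#' steps where the fixation target is 1 — stimulus and delay — exceeds 0.5;
#' set `fix_rule = "per_step"` to require every such step to exceed it).
#' Otherwise the outputs averaged over the response phase are compared to
#' the target: choice tasks (`DM`, `CtxDM`, `Romo`) are correct when the
#' response average of the output whose target is 1 exceeds the other;
#' repeat tasks (`Go`, `GoRt`, `GoDl`) are correct when the corresponding
#' output average is within `repeat_tol` of the target amplitude.
#'
#' The ground truth is the deterministic stimulus mean recorded in the trial
#' specification (the generator knows it, so no realized-noise ambiguity).
#'
#' @param trace A `spikecog_trace`; may include leading padding steps (the
#'   trailing steps matching the spec's timing are scored).
#' @param spec The trial's `spikecog_trial_spec`.
#' @param fix_threshold Fixation criterion threshold (default 0.5).
#' @param repeat_tol Absolute tolerance for repeat tasks (default 0.15).
#' @param fix_rule `"mean"` (default) or `"per_step"`.
#' @param romo_first_larger_wins Romo polarity flag (see [render_trial()]).
#' @return A `spikecog_outcome` list: `mean_outputs` (response-phase means
#'   of `y1`, `y2`), `mean_fix` (fixation-phase mean of `y_fix`),
#'   `fixation_ok`, `correct`, `target`.
#' @export
score_trial <- function(trace, spec, fix_threshold = 0.5,
                        repeat_tol = 0.15, fix_rule = c("mean", "per_step"),
                        romo_first_larger_wins = TRUE) {
  fix_rule <- match.arg(fix_rule)
  ref <- render_phase(spec)
  n <- length(ref)
  Y <- trace$Y
  if (nrow(Y) < n) stop("trace shorter than the trial specification")
  Y <- Y[(nrow(Y) - n + 1):nrow(Y), , drop = FALSE]

  resp <- ref == "response"
  if (!any(resp)) stop("empty response phase")
  hold <- !resp
  yfix <- Y[hold, 1]
  fixation_ok <- if (fix_rule == "mean") mean(yfix) > fix_threshold
  else all(yfix > fix_threshold)

  mean_out <- colMeans(Y[resp, 2:3, drop = FALSE])
  tgt <- .trial_target(spec, romo_first_larger_wins)
  correct <- if (!fixation_ok) FALSE
  else if (tgt$type == "choice")
    mean_out[tgt$winner] > mean_out[3L - tgt$winner]
  else abs(mean_out[tgt$channel] - tgt$value) <= repeat_tol

  structure(list(mean_outputs = unname(mean_out), mean_fix = mean(yfix),
                 fixation_ok = fixation_ok, correct = as.logical(correct),
                 target = tgt),
            class = "spikecog_outcome")
}

#' Phase labels implied by a trial specification
#'
#' Deterministic reconstruction of the per-step phase sequence (no noise is
#' involved in the phase structure), used by the scorer.
#'
#' @param spec A `spikecog_trial_spec`.
#' @return Character vector of per-step phase labels.
#' @export
render_phase <- function(spec) {
  n_stim <- as.integer(round(spec$T_stim / spec$dt))
  n_delay <- as.integer(round(spec$T_delay / spec$dt))
  n_resp <- as.integer(round(spec$T_resp / spec$dt))
  switch(spec$family,
    Romo = c(rep("stimulus", n_stim), rep("delay", n_delay),
             rep("stimulus", n_stim), rep("response", n_resp)),
    GoDl = c(rep("stimulus", n_stim), rep("delay", n_delay),
             rep("response", n_resp)),
    c(rep("stimulus", n_stim), rep("response", n_resp)))
}

#' Evaluate task performance of a network
#'
#' Runs the testing protocol: `n_trials` trials of randomly selected tasks
#' (the default protocol, 100 trials) or `n_trials` per task
#' (`protocol = "per_task"`), each freshly sampled, rendered, simulated from
#' the zero state and scored with [score_trial()].
#'
#' @param w A `spikecog_weights`.
#' @param p A `spikecog_neuron_params`.
#' @param tasks Task names to draw from.
#' @param n_trials Number of test trials (total for `"random"`, per task for
#'   `"per_task"`).
#' @param sigma Sensory noise standard deviation.
#' @param kappa Readout filter parameter.
#' @param dt Time step, ms.
#' @param seed Optional seed for reproducible evaluation.
#' @param protocol `"random"` or `"per_task"`.
#' @param T_stim_range Optional stimulus-duration override, ms.
#' @param ... Passed to [score_trial()].
#' @return A `spikecog_performance` list: `per_task` (named accuracy
#'   vector, `NaN` for tasks never drawn), `overall` (fraction of correct
#'   trials), `n_trials`, `outcomes`.
#' @export
evaluate <- function(w, p = neuron_params(nrow(w$W_rec)),
                     tasks = spikecog_tasks(), n_trials = 100,
                     sigma = 0.05, kappa = exp(-1 / 2), dt = 1,
                     seed = NULL, protocol = c("random", "per_task"),
                     T_stim_range = NULL, ...) {
  protocol <- match.arg(protocol)
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  drawn <- if (protocol == "random")
    sample(tasks, n_trials, replace = TRUE)
  else rep(tasks, each = n_trials)

  outcomes <- lapply(drawn, function(tk) {
    spec <- sample_trial_spec(tk, noise_sigma = sigma, dt = dt,
                              T_stim_range = T_stim_range)
    trace <- simulate_trial(w, render_trial(spec), p, kappa, dt)
    score_trial(trace, spec, ...)
  })
  correct <- vapply(outcomes, `[[`, TRUE, "correct")
  per_task <- vapply(tasks, function(tk) {
    idx <- drawn == tk
    if (!any(idx)) NaN else mean(correct[idx])
  }, 1.0)
  structure(list(per_task = per_task, overall = mean(correct),
                 n_trials = n_trials, tasks = drawn, outcomes = outcomes),
            class = "spikecog_performance")
}

#' Per-neuron mean firing rates by task and trial
#'
#' Runs `n_trials` freshly sampled trials of each task, computes each
#' neuron's mean firing rate (Hz) over the chosen trial phase, and arranges
#' them into the `N x (N_task * N_trials)` data matrix used for clustering
#' (columns grouped by task, trials within task).  The matrix normalized to
#' its maximum entry is stored alongside.
#'
#' @param w,p,tasks,sigma,kappa,dt,seed As in [evaluate()].
#' @param n_trials Trials per task (clustering default 100).
#' @param phase `"stimulus"` (stimulus plus delay steps), `"response"`, or
#'   `"whole"`.
#' @return A `spikecog_rate_table`: `K` (rates, Hz), `K_norm` (`K` divided
#'   by its maximum entry; zero matrix stays zero), `normalization`,
#'   `tasks`, `n_trials`, `phase`.
#' @export
mean_rate_table <- function(w, p = neuron_params(nrow(w$W_rec)),
                            tasks = spikecog_tasks(), n_trials = 100,
                            phase = c("stimulus", "response", "whole"),
                            sigma = 0.05, kappa = exp(-1 / 2), dt = 1,
                            seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(w$W_rec)
  K <- matrix(0, N, length(tasks) * n_trials)
  col <- 0L
  for (tk in tasks) {
    for (i in seq_len(n_trials)) {
      col <- col + 1L
      spec <- sample_trial_spec(tk, noise_sigma = sigma, dt = dt)
      trial <- render_trial(spec)
      trace <- simulate_trial(w, trial, p, kappa, dt)
      keep <- switch(phase,
        stimulus = trial$phase %in% c("stimulus", "delay"),
        response = trial$phase == "response",
        whole = rep(TRUE, length(trial$phase)))
      K[, col] <- colMeans(trace$Z[keep, , drop = FALSE]) * 1000 / dt
    }
  }
  colnames(K) <- paste0(rep(tasks, each = n_trials), "_",
                        rep(seq_len(n_trials), length(tasks)))
  mx <- max(K)
  structure(list(K = K, K_norm = if (mx > 0) K / mx else K,
                 normalization = mx, tasks = tasks, n_trials = n_trials,
                 phase = phase),
            class = "spikecog_rate_table")
}
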