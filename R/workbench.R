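#' Derive a named sub-seed from a master seed
#'
#' One master seed spawns independent named streams (weights, trials,
#' noise, restarts, ...) so components can be re-run in isolation while the
#' whole experiment stays reproducible.  The derivation is a fixed integer
#' hash kept below 2^31.
#'
#' @param master Integer master seed.
#' @param stream Stream name (character).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stream) {
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(stream))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Experiment run configuration
#'
#' @param N Network size.
#' @param tasks Task subset to train/evaluate on.
#' @param train A `spikecog_train_config`.
#' @param params Optional `spikecog_neuron_params` overrides (defaults by
#'   `N`).
#' @param eval_trials Test trials for evaluation.
#' @param master_seed Master seed; per-component seeds come from
#'   [derive_seed()].
#' @return A `spikecog_run_config`.
#' @export
run_config <- function(N, tasks = spikecog_tasks(),
                       train = train_config(), params = NULL,
                       eval_trials = 100, master_seed = 1L) {
  if (is.null(params)) params <- neuron_params(N)
  structure(list(N = as.integer(N), tasks = tasks, train = train,
                 params = params, eval_trials = as.integer(eval_trials),
                 master_seed = as.integer(master_seed)),
            class = "spikecog_run_config")
}

#' Save / load a run configuration (JSON)
#'
#' Round-trips exactly: `load_config(save_config(cfg, path))` reproduces
#' the configuration, numeric fields at full precision.
#'
#' @param cfg A `spikecog_run_config`.
#' @param path File path.
#' @return `load_config` returns the `spikecog_run_config`;
#'   `save_config` returns `path` invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "spikecog_run_config"))
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- raw$train
  cfg <- train_config(
    loss_variant = tr$loss_variant, lambda_reg = tr$lambda_reg,
    f_th = tr$f_th, eta = tr$eta, n_epoch = tr$n_epoch,
    n_batch = tr$n_batch, alpha = tr$alpha, tau_out = tr$tau_out,
    mask_values = tr$mask_values, optimizer = tr$optimizer,
    adam = tr$adam, denominator = tr$denominator, sigma = tr$sigma,
    dt = tr$dt, seed = tr$seed, T_stim_range = tr$T_stim_range,
    eval_every = tr$eval_every, eval_trials = tr$eval_trials,
    checkpoint_every = tr$checkpoint_every,
    checkpoint_dir = tr$checkpoint_dir)
  p <- raw$params
  run_config(N = raw$N, tasks = raw$tasks, train = cfg,
             params = neuron_params(tau_m = p$tau_m, tau_a = p$tau_a,
                                    tau_s = p$tau_s, v_th = p$v_th,
                                    v_reset = p$v_reset, theta = p$theta,
                                    a_s = p$a_s, a_current = p$a_current),
             eval_trials = raw$eval_trials, master_seed = raw$master_seed)
}

# strip S3 classes recursively for JSON serialization
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Bundle a checkpoint
#'
#' @param weights A `spikecog_weights`.
#' @param params A `spikecog_neuron_params`.
#' @param config The training or run configuration snapshot.
#' @param epoch Epoch index of the snapshot.
#' @return A `spikecog_checkpoint` (self-describing; re-loadable without
#'   external context).
#' @export
make_checkpoint <- function(weights, params, config = NULL, epoch = 0L) {
  structure(list(schema = "spikecog_checkpoint_v1", weights = weights,
                 params = params, config = config,
                 epoch = as.integer(epoch)),
            class = "spikecog_checkpoint")
}

#' Save / load a checkpoint
#'
#' Single-file container with the weight matrices, neuron parameters,
#' configuration snapshot and epoch index.  Weights round-trip bit-exactly.
#' Corrupt or truncated files raise an explicit corruption error; files
#' with an unknown schema raise a schema-version error.
#'
#' @param ckpt A `spikecog_checkpoint`.
#' @param path File path.
#' @return `load_checkpoint` returns the `spikecog_checkpoint`;
#'   `save_checkpoint` returns `path` invisibly.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "spikecog_checkpoint"))
  saveRDS(ckpt, path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ckpt <- tryCatch(readRDS(path),
                   error = function(e)
                     stop("corrupt checkpoint file: ", path,
                          " (", conditionMessage(e), ")", call. = FALSE))
  if (!inherits(ckpt, "spikecog_checkpoint") ||
      !identical(ckpt$schema, "spikecog_checkpoint_v1"))
    stop("checkpoint schema mismatch in ", path)
  ckpt
}

#' Export a rendered trial to CSV
#'
#' Writes one trial's inputs, targets and phase labels as a flat CSV
#' (one row per time step).
#'
#' @param trial A `spikecog_trial`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "spikecog_trial"))
  df <- data.frame(step = seq_len(nrow(trial$inputs)),
                   phase = trial$phase, trial$inputs, trial$targets,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic small test fixtures
#'
#' @param kind `"tiny_net"` (a 3-neuron network with weights and
#'   parameters), `"canned_trials"` (three short rendered trials on the dt
#'   grid), or `"planted_rate_table"` (an 8-neuron rate table with two
#'   planted, well-separated clusters).
#' @param seed Seed; identical seeds give identical fixtures.
#' @return The fixture object.
#' @export
make_fixture <- function(kind = c("tiny_net", "canned_trials",
                                  "planted_rate_table"), seed = 0L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    tiny_net = list(weights = init_weights(3), params = neuron_params(3)),
    canned_trials = {
      mk <- function(task, T_stim, T_delay = 0, T_resp = 8, a = 0.7) {
        spec <- structure(list(task = task, family = task_id(task)$family,
                               modality = task_id(task)$modality,
                               T_stim = T_stim, T_delay = T_delay,
                               T_resp = T_resp,
                               a_stim = if (task_id(task)$family %in%
                                            c("CtxDM", "Romo"))
                                 c(a, 1 - a) else a,
                               noise_sigma = 0.05, dt = 1, u_th = 0.5),
                          class = "spikecog_trial_spec")
        render_trial(spec)
      }
      list(mk("DM1", 12), mk("Go2", 10), mk("Romo1", 4, T_delay = 4))
    },
    planted_rate_table = {
      centers <- rbind(c(5, 5, 40, 40), c(40, 40, 5, 5))
      lab <- rep(1:2, each = 4)
      K <- centers[lab, ] + matrix(rnorm(8 * 4, 0, 0.5), 8, 4)
      K <- pmax(K, 0)
      structure(list(K = K, K_norm = K / max(K), normalization = max(K),
                     tasks = paste0("task", 1:4), n_trials = 1,
                     phase = "whole", planted_labels = lab),
                class = "spikecog_rate_table")
    })
}
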