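#' @useDynLib spikecog, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
#' @importFrom utils head write.csv
NULL

# Fixed bijection between task ids and one-hot indices.  Six task families,
# each implemented through one of the two sensory modalities.
.task_families <- c("DM", "CtxDM", "Go", "GoRt", "GoDl", "Romo")

#' Task identifiers of the cognitive battery
#'
#' The battery contains six task families (decision making `DM`, context
#' decision making `CtxDM`, go/no-go `Go`, reaction-time go `GoRt`, delayed go
#' `GoDl`, and the working-memory comparison task `Romo`), each implemented
#' through one of two sensory modalities, giving twelve target tasks.  The
#' returned order ("DM1", "DM2", "CtxDM1", ..., "Romo2") is the fixed
#' bijection onto the one-hot task-coding vector.
#'
#' @return Character vector of the twelve task names, in one-hot index order.
#' @export
#' @examples
#' spikecog_tasks()
spikecog_tasks <- function() {
  as.vector(t(outer(.task_families, 1:2, paste0)))
}

#' Parse a task name into family and modality
#'
#' @param task Task name, e.g. `"DM1"` or `"Romo2"`.
#' @return List with elements `family` (character) and `modality` (1 or 2).
#' @export
task_id <- function(task) {
  all <- spikecog_tasks()
  if (!is.character(task) || length(task) != 1L || !(task %in% all))
    stop("unknown task id: ", paste(task, collapse = ", "))
  modality <- as.integer(substring(task, nchar(task)))
  family <- substring(task, 1L, nchar(task) - 1L)
  list(family = family, modality = modality)
}

#' One-hot task-coding vector
#'
#' During a trial the unit corresponding to the current task equals 1 and all
#' other units are 0.
#'
#' @param task Task name (see [spikecog_tasks()]).
#' @return Numeric vector of length 12 with a single 1 at the task's index.
#' @export
one_hot_task_vector <- function(task) {
  all <- spikecog_tasks()
  task_id(task)  # validates
  v <- numeric(length(all))
  v[match(task, all)] <- 1
  v
}

# Round a duration in ms onto the dt grid, keeping it positive.
.grid <- function(x, dt) max(dt, round(x / dt) * dt)

#' Sample the parameters of one task trial
#'
#' Durations are drawn from the continuous uniform ranges of the task
#' parameter table (stimulus/fixation duration, delay where used, fixed
#' response duration) and rounded onto the `dt` grid; stimulus amplitudes are
#' drawn from U(0, 1) for `DM`/`CtxDM`/`Romo` and from the discrete 8-level
#' set {0, 1/7, ..., 6/7, 1} for the go-family tasks.  Draws come from R's
#' global random number stream.
#'
#' @param task Task name.
#' @param noise_sigma Standard deviation of the additive Gaussian sensory
#'   noise (dimensionless input units).
#' @param dt Time step in ms.
#' @param u_th Decision threshold for `DM`/`CtxDM` (dimensionless).
#' @param T_stim_range Optional length-2 override of the stimulus/fixation
#'   duration range in ms (used by scaled-down training protocols).
#' @return A `spikecog_trial_spec` list: `task`, `family`, `modality`,
#'   `T_stim`, `T_delay` (0 when unused), `T_resp`, `a_stim` (one amplitude,
#'   or two for `CtxDM`/`Romo`), `noise_sigma`, `dt`, `u_th`.
#' @export
#' @examples
#' set.seed(1)
#' sample_trial_spec("DM1")
sample_trial_spec <- function(task, noise_sigma = 0.05, dt = 1, u_th = 0.5,
                              T_stim_range = NULL) {
  id <- task_id(task)
  go_levels <- (0:7) / 7
  rng_stim <- switch(id$family,
    DM = , CtxDM = , Go = , GoRt = c(300, 1800),
    GoDl = , Romo = c(200, 600))
  if (!is.null(T_stim_range)) rng_stim <- T_stim_range
  T_stim <- .grid(runif(1, rng_stim[1], rng_stim[2]), dt)
  T_delay <- if (id$family %in% c("GoDl", "Romo"))
    .grid(runif(1, 200, 1700), dt) else 0
  T_resp <- if (id$family == "GoRt") 1500 else 250
  a_stim <- switch(id$family,
    DM = runif(1),
    CtxDM = runif(2),           # (modality-1 mean, modality-2 mean)
    Romo = runif(2),            # (first pulse, second pulse)
    Go = , GoRt = , GoDl = sample(go_levels, 1))
  structure(list(task = task, family = id$family, modality = id$modality,
                 T_stim = T_stim, T_delay = T_delay, T_resp = T_resp,
                 a_stim = a_stim, noise_sigma = noise_sigma,
                 dt = dt, u_th = u_th),
            class = "spikecog_trial_spec")
}

#' Render a trial specification into input/target/mask time series
#'
#' Builds the `[N_step x N_in]` input matrix (fixation channel, two noisy
#' sensory channels, 12-unit one-hot task block), the `[N_step x 3]` target
#' matrix (columns `y_fix`, `y1`, `y2`), and per-step phase labels
#' (`"stimulus"`, `"delay"`, `"response"`).  The fixation input is 1 during
#' the stimulus (and delay) phase and 0 during the response phase; in the
#' reaction-time task `GoRt` it is held at 1 for the whole trial and the
#' fixation *target* drops to 0 after stimulus onset.  Sensory channels are a
#' deterministic profile plus N(0, sigma) noise at every step.  The fixation
#' target replicates the fixation input (`GoRt` excepted, as above); choice
#' tasks have a binary (y1, y2) response target decided by the deterministic
#' stimulus means, repeat tasks reproduce the stimulus amplitude on the
#' corresponding output channel.
#'
#' @param spec A `spikecog_trial_spec`.
#' @param romo_first_larger_wins If `TRUE` (default) the Romo target is
#'   (1, 0) when the first pulse amplitude exceeds the second.
#' @return A `spikecog_trial` list: `inputs`, `targets`, `phase` (character
#'   vector), `spec`.
#' @export
render_trial <- function(spec, romo_first_larger_wins = TRUE) {
  stopifnot(inherits(spec, "spikecog_trial_spec"))
  dt <- spec$dt
  durs <- c(spec$T_stim, spec$T_delay, spec$T_resp)
  if (any(abs(durs / dt - round(durs / dt)) > 1e-9))
    stop("trial durations must be multiples of dt")
  n_stim <- as.integer(round(spec$T_stim / dt))
  n_delay <- as.integer(round(spec$T_delay / dt))
  n_resp <- as.integer(round(spec$T_resp / dt))
  m <- spec$modality
  fam <- spec$family

  phase <- switch(fam,
    Romo = c(rep("stimulus", n_stim), rep("delay", n_delay),
             rep("stimulus", n_stim), rep("response", n_resp)),
    GoDl = c(rep("stimulus", n_stim), rep("delay", n_delay),
             rep("response", n_resp)),
    c(rep("stimulus", n_stim), rep("response", n_resp)))
  n_step <- length(phase)

  u_mod <- matrix(0, n_step, 2)     # deterministic sensory profiles
  resp <- phase == "response"
  if (fam == "DM") {
    u_mod[!resp, m] <- spec$a_stim
  } else if (fam == "CtxDM") {
    u_mod[!resp, 1] <- spec$a_stim[1]
    u_mod[!resp, 2] <- spec$a_stim[2]
  } else if (fam == "Go") {
    u_mod[, m] <- spec$a_stim       # input stays on during the whole trial
  } else if (fam == "GoRt") {
    u_mod[resp, m] <- spec$a_stim   # switched on at the random onset moment
  } else if (fam == "GoDl") {
    u_mod[phase == "stimulus", m] <- spec$a_stim
  } else if (fam == "Romo") {
    stim_idx <- which(phase == "stimulus")
    u_mod[stim_idx[seq_len(n_stim)], m] <- spec$a_stim[1]
    u_mod[stim_idx[n_stim + seq_len(n_stim)], m] <- spec$a_stim[2]
  }

  u_fix <- if (fam == "GoRt") rep(1, n_step) else as.numeric(!resp)

  inputs <- cbind(u_fix,
                  u_mod + matrix(rnorm(2 * n_step, 0, spec$noise_sigma),
                                 n_step, 2),
                  matrix(one_hot_task_vector(spec$task), n_step, 12,
                         byrow = TRUE))
  colnames(inputs) <- c("u_fix", "u_mod1", "u_mod2",
                        paste0("u_task_", spikecog_tasks()))

  targets <- matrix(0, n_step, 3,
                    dimnames = list(NULL, c("y_fix", "y1", "y2")))
  targets[, "y_fix"] <- as.numeric(!resp)   # GoRt included: 0 after onset
  if (fam %in% c("DM", "CtxDM")) {
    mean_of_interest <- if (fam == "DM") spec$a_stim else spec$a_stim[m]
    choice <- if (mean_of_interest < spec$u_th) c(1, 0) else c(0, 1)
    targets[resp, c("y1", "y2")] <- matrix(choice, sum(resp), 2, byrow = TRUE)
  } else if (fam == "Romo") {
    first_larger <- spec$a_stim[1] > spec$a_stim[2]
    win <- xor(first_larger, !romo_first_larger_wins)
    choice <- if (win) c(1, 0) else c(0, 1)
    targets[resp, c("y1", "y2")] <- matrix(choice, sum(resp), 2, byrow = TRUE)
  } else {
    targets[resp, c("y1", "y2")[m]] <- spec$a_stim
  }

  structure(list(inputs = inputs, targets = targets, phase = phase,
                 spec = spec),
            class = "spikecog_trial")
}

#' Assemble rendered trials into an aligned batch
#'
#' Trials are aligned to the longest trial in the batch by prepending steps
#' with all-zero inputs (every input channel, including the task-coding
#' block).  The loss mask equals the stimulus-phase weight during stimulus
#' and delay steps, the response-phase weight during response steps, and 0 on
#' padding steps (padding carries no learning signal).
#'
#' @param trials Non-empty list of `spikecog_trial` objects.
#' @param mask_values Length-2 numeric `(stimulus weight, response weight)`;
#'   `c(1, 5)` for the pure mean-squared-error loss, `c(0.1, 1)` for the
#'   rate-regularized variant.
#' @return A `spikecog_batch` list with arrays `inputs`
#'   `[N_step x N_batch x N_in]`, `targets` and `mask`
#'   `[N_step x N_batch x 3]`, character matrix `phase`
#'   `[N_step x N_batch]` (padding steps labelled `"padding"`), and the list
#'   of trial `specs`.
#' @export
assemble_batch <- function(trials, mask_values = c(1, 5)) {
  if (length(trials) == 0L) stop("empty trial list")
  stopifnot(all(vapply(trials, inherits, TRUE, "spikecog_trial")),
            length(mask_values) == 2L)
  n_in <- ncol(trials[[1]]$inputs)
  n_out <- ncol(trials[[1]]$targets)
  lens <- vapply(trials, function(tr) nrow(tr$inputs), 1L)
  n_step <- max(lens)
  nb <- length(trials)

  inputs <- array(0, c(n_step, nb, n_in))
  targets <- array(0, c(n_step, nb, n_out))
  mask <- array(0, c(n_step, nb, n_out))
  phase <- matrix("padding", n_step, nb)

  for (b in seq_len(nb)) {
    tr <- trials[[b]]
    idx <- (n_step - lens[b] + 1):n_step
    inputs[idx, b, ] <- tr$inputs
    targets[idx, b, ] <- tr$targets
    phase[idx, b] <- tr$phase
    w <- ifelse(tr$phase == "response", mask_values[2], mask_values[1])
    mask[idx, b, ] <- matrix(w, lens[b], n_out)
  }
  structure(list(inputs = inputs, targets = targets, mask = mask,
                 phase = phase, specs = lapply(trials, `[[`, "spec")),
            class = "spikecog_batch")
}
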