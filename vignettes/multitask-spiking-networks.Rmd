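---
title: "Multitask spiking recurrent networks: model, training and reverse engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask spiking recurrent networks: model, training and reverse engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecog)
```

## The model

`spikecog` simulates and trains a recurrent network of $N$ adaptive
exponential (AdEx) integrate-and-fire neurons in discrete time (Euler
scheme, $\Delta t = 1$ ms).  Each neuron carries a membrane potential
$v_j$, an adaptation variable $a_j$ and a synaptic current $I_j$:

$$
\begin{aligned}
v_j(n+1) &= v_j(n) + \frac{\Delta t}{\tau_m}\Big(-v_j(n) +
  \theta e^{(v_j(n)-v_{th})/\theta} + I_j(n) - a_j(n)\Big),\\
a_j(n+1) &= a_j(n) + \frac{\Delta t}{\tau_a}\big(a_{current}\,v_j(n) -
  a_j(n)\big),\\
I_j(n+1) &= I_j(n)\Big(1-\frac{\Delta t}{\tau_s}\Big) +
  \sum_k w^{in}_{jk} u_k(n+1) + \sum_k w^{rec}_{jk} z_k(n),
\end{aligned}
$$

with spikes $z_j(n) = H(v_j(n) - v_{th})$, where $H$ is the Heaviside step
with the convention $H(0) = 1$.  When a neuron spikes it is reset,
$v \to v_{reset}$ and $a \to a + a_s$, *before* the next Euler update; the
spike indicator is always evaluated from the pre-reset membrane potential,
so each threshold crossing yields exactly one spike.  The default
parameters are $\tau_m = 10$ ms, $\tau_a = 2$ s, $\tau_s = 5$ ms,
$v_{th} = 0.65$ mV ($0.45$ mV for $N = 256$), $v_{reset} = 0$,
$\theta = 0.5$ mV, $a_s = 0.02$, $a_{current} = 4$; all quantities enter
the updates as these dimensionless numbers.  The slow adaptation variable
gives the model its working-memory capacity: under a sustained
suprathreshold input, firing slows and eventually stops as $a$
accumulates, and resumes after a silent gap (`simulate_trial()` reproduces
this single-neuron phenomenology, see `tests/testthat/test-adex-network.R`).

The argument of the spike-initiation exponential is capped at $+20$ before
exponentiation.  Untrained networks can transiently diverge, and the cap
keeps the forward pass finite without affecting any membrane potential
within ten millivolts of threshold.

Outputs are exponential filters of the spike trains,
$y_j(n+1) = \kappa y_j(n) + \sum_k w^{out}_{jk} z_k(n) + b_j$ with
$\kappa = e^{-\Delta t/\tau_{out}}$.

Recurrent and input weights are initialized as $\sqrt{2/N}\,\mathcal
N(0,1)$, the readout as $\mathcal U(-\sqrt{1/N}, \sqrt{1/N})$.  The
diagonal of $W^{rec}$ is held at zero by every weight-writing operation —
no self-excitation — and no sign structure (Dale's principle) is imposed.

## The task battery

Twelve target tasks arise from six families, each driven through one of
two sensory modalities: decision making (`DM`), context-dependent decision
making (`CtxDM`), a two-pulse working-memory comparison (`Romo`), and
three go/no-go variants (`Go`, `GoRt`, `GoDl`).  Inputs are a binary
fixation channel, two noisy sensory channels
($u = u_0 + \mathcal N(0, \sigma)$ at every step) and a 12-unit one-hot
task code, $N_{in} = 15$; outputs are a fixation channel and two response
units.  Trials have a stimulus phase (fixation input 1) and a response
phase (fixation input 0); stimulus durations are drawn uniformly
(300–1800 ms for `DM`/`CtxDM`/`Go`/`GoRt`, 200–600 ms for `GoDl`/`Romo`,
delays 200–1700 ms), response phases last 250 ms (1500 ms for `GoRt`).
Choice-task amplitudes are $\mathcal U(0,1)$; go-family amplitudes come
from the discrete set $\{0, \tfrac17, \dots, \tfrac67, 1\}$.

Two design points deserve comment because the underlying experimental
designs admit two readings:

* **Held fixation.** We assign the held-fixation exception to the
  reaction-time task: `GoRt` keeps the fixation *input* at 1 for the whole
  trial and the stimulus onset (after a 300–1800 ms fixation period) cues
  the response, with the fixation *target* dropping to 0 at onset — the
  network must learn to suppress its fixation output.  `GoDl`'s response
  is cued by the fixation input switching off after the delay.  This is
  the assignment consistent with the reaction-time design (there is no
  external cue other than the stimulus itself) and with the delayed-go
  design (the fixation offset is the only possible response cue).
* **Romo polarity.** The target is $(y_1, y_2) = (1, 0)$ when the *first*
  pulse is larger.  Both conventions appear in the experimental
  literature on the two-interval comparison task;
  `render_trial(..., romo_first_larger_wins = FALSE)` flips it.

The sensory noise level is a free parameter of the battery; the
package default is $\sigma = 0.05$, a value at which near-threshold decision
trials remain genuinely uncertain while clearly separated amplitudes are
reliably discriminable.  It is exposed everywhere a trial is sampled.

Decision ground truth uses the deterministic stimulus mean $u_0$, not the
realized noisy average: trials are generated, so $u_0$ is known exactly
and scoring is unambiguous.

Batches align trials to the longest by *prepending* steps whose inputs are
all zero, including the task-coding block.  The loss mask is the
stimulus-phase weight on stimulus and delay steps, the response-phase
weight on response steps, and 0 on padding — padding carries no learning
signal.

## Training

The loss is a masked mean-squared error with the full product
normalization $N_{out} N_{batch} N_{step} \sum m$; `masked_mse()` and the
trainer implement this form, with a configuration switch
(`denominator = "mask_sum"`) for the conventional mask-weighted mean
$\sum m$.  The two differ by the constant factor
$N_{out} N_{batch} N_{step}$ only.  Two variants are supported:

* `"mse"` — mask weights (1, 5), $\tau_{out} = 2$ ms, batch 50;
* `"mse_plus_rate_reg"` — adds $\lambda E_r$ with
  $E_r = \sum_i f_i H(f_i - f_{th})$, $f_i$ the mean rate in Hz over batch
  and time and $f_{th} = 30$ Hz; mask weights (0.1, 1),
  $\tau_{out} = 50$ ms, batch 32, $v_{th} = 0.45$ for $N = 256$.  The
  regularizer weight $\lambda$ is a free parameter; the default
  is $\lambda = 1$, exposed in the configuration.

Gradients flow through the spike nonlinearity via the SuperSpike
pseudo-derivative $\sigma'_j = (1 + |\alpha(v_j - v_{th})|)^{-2}$,
$\alpha = 100$, on the gradient path only; the forward pass always uses
the hard threshold.  Sensitivities of membrane potentials and adaptation
variables propagate by the forward recursions

$$
\begin{aligned}
\frac{\partial V_j(n)}{\partial w_{jk}} &=
 \frac{\partial V_j(n-1)}{\partial w_{jk}}
 \Big[1 + \frac{\Delta t}{\tau_m}\big(e^{(V_j(n-1)-v_{th})/\theta} -
 1\big)\Big] + \frac{\Delta t}{\tau_m}\Big(d_k -
 \frac{\partial a_j(n-1)}{\partial w_{jk}}\Big),\\
\frac{\partial a_j(n)}{\partial w_{jk}} &=
 \frac{\partial a_j(n-1)}{\partial w_{jk}}
 \Big(1 - \frac{\Delta t}{\tau_a}\Big) + \frac{\Delta t}{\tau_a}
 a_{current} \frac{\partial V_j(n-1)}{\partial w_{jk}},
\end{aligned}
$$

with drive $d_k = z_k(n-1)$ for recurrent weights (the presynaptic spike;
with $I_j = \sum_k w_{jk} z_k$ the derivative of $I_j$ with respect to
$w_{jk}$ is $z_k$) and $d_k = u_k(n)$ for input weights.  The recursions
define a *per-neuron-local* computational graph: recurrent spike inputs
are treated as constants of the previous step, reset jumps carry no
gradient, and the synaptic filter's weight sensitivity is taken as
instantaneous.  The input-weight sensitivities carry the same $(V, a)$
coupling as the recurrent ones — the adaptation line applies to both weight
classes.  Readout weights and biases use the exact chain rule through the
exponential filter.

`forward_sensitivities()` implements the recursions literally (one
sensitivity per weight; intended for small instances and verification).
`train()` uses the reverse-mode *adjoint* accumulation of the identical
recursions in compiled code: a backward sweep of per-neuron adjoint pairs
followed by three matrix products per trial.  The two routes agree to
machine precision, and both agree with an independent reverse-mode
backpropagation-through-time oracle in the test suite (relative error
below $10^{-6}$ on small random instances).

Updates use Adam with standard coefficients ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) or plain SGD.  The learning-rate
preset is $\{5\times10^{-2}, 5\times10^{-3}, 5\times10^{-4}\}$ with
$5\times10^{-3}$ the default (the best-performing value).  Gradient
diagonals of $W^{rec}$ are zeroed before the update and the weight
diagonal re-zeroed after it.

Two ready-made protocols are exposed.  `full_scale_protocol()` is the
performance-level configuration (600 neurons, all 12 tasks, 3000 epochs,
batch 50 for the pure-MSE loss; 256 neurons, batch 32 for the regularized
loss) — a multi-CPU-hour run.  `scaled_down_protocol()` is the desk-scale
surrogate used by the test suite and the acceptance script: 128 neurons,
tasks DM1/DM2/Go1/Go2, stimulus durations $\mathcal U(200, 500)$ ms, batch
16, 500 epochs.  The scaled protocol uses the `"mask_sum"` loss
normalization: the printed normalization divides by batch size and trial
length, which at desk scale pushes raw gradient magnitudes toward Adam's
$\epsilon$ floor; the weighted-mean form keeps the loss $O(1)$ and is the
same objective up to a constant factor.  This run finishes in about a
minute and reaches roughly 95–98% accuracy over 100 test trials (seeds
vary within a few percent).

## Accuracy protocol

A test trial fails outright unless the fixation criterion holds: the
fixation output must exceed 0.5.  The package tests the *mean* of
$y_{fix}$ over the steps whose fixation target is 1 (stimulus and
delay), which is the phase where the target is defined, with a per-step
variant available
(`score_trial(..., fix_rule = "per_step")`).  Choice tasks are correct
when the response-phase average of the output whose target is 1 exceeds
the other; repeat tasks when the corresponding output average is within
0.15 of the target amplitude (the tolerance, nominally "approximately
0.15", is implemented as exactly 0.15).  `evaluate()` runs 100 trials of randomly
selected tasks by default, or a per-task protocol.

## Reverse engineering

* **PCA** (`build_state_matrix()`, `pca_project()`): membrane potentials
  and adaptation variables are analyzed separately because of their time
  scales; rows (neurons) are mean-centered, with no variance scaling, and
  the top three components are taken by default.  Which trials are pooled
  into the data matrix is left to the caller (e.g. minimum and maximum
  stimulus values only).
* **Demixed decomposition** (`dpca_decompose()`): condition-averaged rates
  $X[n, s, d, t]$ split additively into a time component, a stimulus
  component (stimulus effect per time, averaged over decisions), a
  decision component, and a residual (the stimulus–decision interaction).
  This is the marginalization-average decomposition only — no reduced-rank
  regression or regularization; the terms reconstruct the tensor exactly,
  are orthogonal in balanced designs, and per-marginalization PCA
  (`dpca_components()`) yields the demixed component time courses.
  Instantaneous rates use a causal 50 ms boxcar (`smooth_rates()`),
  configurable.
* **Clustering** (`mean_rate_table()`, `kmeans_cluster()`,
  `ward_linkage()`): per-neuron mean rates per task and phase (100 trials
  per task by default) are assembled into an
  $N \times (N_{task} N_{trials})$ matrix normalized to its maximum
  entry.  k-means minimizes the within-cluster quadratic deviation (Lloyd
  iterations, best of several restarts; a start that collapses to an
  empty cluster is re-seeded).  Ward linkage reports merge costs on the
  ESS-increase scale $R(A, B) = \mathrm{ESS}(A \cup B) - \mathrm{ESS}(A)
  - \mathrm{ESS}(B)$, applied to neurons or to the task axis (task
  dendrogram).  The cluster count is a free parameter;
  `select_k_silhouette()` picks $k \in [2, 20]$ by maximum mean
  silhouette, and $k$ is always exposed.
* **Lesioning** (`lesion()`, `lesion_screen()`): with $I_j = \sum_k W[j,k]
  z_k$, neuron $c$'s outgoing weights are column $c$.  Lesioning zeroes
  the cluster's columns in $W^{rec}$ and $W^{out}$; isolation keeps only
  the cluster's readout columns and cuts recurrent links *into* the
  cluster from outside (input weights are left intact — cutting them too
  is a stricter variant not implied by the stated rule).  The screen
  evaluates each (cluster, task) cell over 200 trials by default.

## Reproducibility and storage

One master seed spawns named substreams (`derive_seed(master, "weights")`,
`"train"`, `"eval"`, ...) so components can be re-run in isolation; a full
train–evaluate–analyze run repeated under the same master seed is
byte-identical.  Checkpoints are single-file, self-describing containers
(R native serialization, version 3) holding the weight matrices, neuron
parameters, configuration snapshot and epoch index, with bit-exact weight
round-trips and explicit corruption and schema errors; run configurations
round-trip through JSON at full numeric precision, and single trials
export to CSV.

## What the synthetic tasks do and do not show

All inputs are synthetic renderings of stylized experimental designs:
piecewise-constant stimulus profiles plus white Gaussian noise, exact
phase boundaries, a noiseless one-hot task cue.  Real recordings have
correlated noise, graded and variable timing, and no ground-truth
amplitude, so passing this battery demonstrates that the *model and
training machinery* behave as specified — not that any conclusion
transfers to a particular dataset.  The test suite deliberately runs at
reduced scale (networks of 3–128 neurons, stimulus durations down to tens
of milliseconds for fixtures, 500-epoch training); these sizes are the
package's choice of a representative yet fast verification regime, while
`full_scale_protocol()` documents the full-size run.  Known limitations:
no conductance-based synapses, transmission delays or Dale-constrained
sign structure; no fixed-point finding or linearization of the trained
dynamics (metastability is described through projected trajectories, not
certified); no statistical testing of cluster significance — cluster
structure varies across network realizations and only its qualitative
features are stable.
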