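# spikecog

Spiking recurrent neural networks that perform multiple
cognitive-neuroscience-inspired tasks, trained by surrogate-gradient
descent and reverse engineered with a population-dynamics toolbox.

Research on "computation through dynamics" trains recurrent networks on
reduced versions of classic animal experiments — perceptual decision
making, context-dependent decisions, parametric working memory, go/no-go —
and then dissects the trained dynamics to ask *how* the network computes.
`spikecog` provides that whole loop for spiking networks of adaptive
exponential (AdEx) integrate-and-fire neurons, for computational
neuroscientists and neuromorphic-computing researchers who want a
correctness-first, fully deterministic reference implementation in R.

## The model

A recurrent network of N AdEx neurons evolves in discrete time
(dt = 1 ms):

    v(n+1) = v(n) + (dt/τ_m) [ −v(n) + θ e^{(v(n)−v_th)/θ} + I(n) − a(n) ]
    a(n+1) = a(n) + (dt/τ_a) [ a_current v(n) − a(n) ]
    I(n+1) = I(n)(1 − dt/τ_s) + W_in u(n+1) + W_rec z(n)

with spikes z = H(v − v_th) (H(0) = 1), reset v → v_reset and
a → a + a_s on spiking, and an exponential-filter readout
y(n+1) = κ y(n) + W_out z(n) + b, κ = e^{−dt/τ_out}.  Twelve tasks (six
families × two sensory modalities) are rendered as input/target/mask time
series — a fixation channel, two noisy sensory channels and a one-hot task
code — and the network is trained end to end on a masked mean-squared
error, optionally with a firing-rate regularizer, using the SuperSpike
pseudo-derivative (1 + |α(v − v_th)|)^−2 on the spike nonlinearity.
Gradients follow per-weight forward sensitivity recursions of the
membrane and adaptation variables; the trainer runs their reverse-mode
(adjoint) equivalent in C++ and the two are tested equal to machine
precision.  The analysis battery covers the accuracy protocol, PCA of
membrane/adaptation trajectories, a demixed (time/stimulus/decision)
marginalization of condition-averaged rates, k-means and Ward clustering
of task-conditioned firing rates, and cluster lesioning/isolation
screens.

## Worked example

Train the desk-scale protocol (128 neurons, tasks DM1/DM2/Go1/Go2, batch
16, 500 epochs, ~1 minute on one CPU) and evaluate it:

```r
library(spikecog)

proto <- scaled_down_protocol(seed = 1)
set.seed(derive_seed(1, "weights"))
w0  <- init_weights(proto$N)
fit <- train(w0, proto$config, proto$tasks, proto$params)

mean(fit$history$loss[1:50])    # 0.107  masked MSE, first 50 epochs
mean(fit$history$loss[451:500]) # 0.030  masked MSE, last 50 epochs

rep <- evaluate(fit$weights, proto$params, proto$tasks, n_trials = 100,
                kappa = exp(-1 / proto$config$tau_out),
                seed = derive_seed(1, "eval"),
                T_stim_range = proto$config$T_stim_range)
rep$per_task
#>   DM1   DM2   Go1   Go2
#>  1.00  1.00  0.93  1.00
rep$overall
#> 0.98
```

The loss falls by a factor of ~3.5 over training and the network solves
98 of 100 random test trials: decision trials are scored by which
response unit is larger on average during the response phase, go trials
by reproducing the stimulus amplitude within 0.15, and every trial must
hold the fixation output above 0.5 until the response cue.

Reverse engineering a trained network follows the same vocabulary:

```r
tab  <- mean_rate_table(fit$weights, proto$params, proto$tasks,
                        n_trials = 20, phase = "response", seed = 2)
part <- kmeans_cluster(tab, k = select_k_silhouette(tab, 2:8)$k)
scr  <- lesion_screen(fit$weights, part, proto$tasks, n_trials = 50,
                      p = proto$params, seed = 3)
scr$lesion          # clusters × tasks accuracy with each cluster silenced
```

The full-size configuration (600 neurons, all 12 tasks, 3000 epochs — a
multi-CPU-hour run) is exposed as `full_scale_protocol()`.  A thin CLI
(`exec/spikecog`) wraps trial generation, training, simulation and
evaluation.  See the vignette
(`vignettes/multitask-spiking-networks.Rmd`) for the model's assumptions,
parameter meanings and design decisions.

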