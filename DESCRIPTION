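Package: spikecog
Title: Multitask Spiking Recurrent Neural Networks Trained by Surrogate
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, training and reverse engineering of discrete-time
    adaptive exponential (AdEx) spiking recurrent neural networks that perform
    a battery of twelve cognitive-neuroscience-inspired tasks (decision
    making, context-dependent decision making, working memory, and go/no-go
    variants).  Networks are trained by surrogate-gradient descent (SuperSpike
    pseudo-derivative) on a masked mean-squared-error loss, optionally with a
    firing-rate regularizer, using forward sensitivity recursions or their
    reverse-mode (adjoint) equivalent implemented in C++.  The analysis
    battery includes the accuracy protocol, principal component projections of
    membrane-potential and adaptation-variable trajectories, demixed PCA
    marginalization, k-means and Ward clustering of task-conditioned firing
    rates, and cluster lesioning/isolation screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
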