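Package: tcedit
Title: Controllable Editing of Multivariate Longitudinal Trajectories via Temporal Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns temporal concepts -- per-variable multiplicative rates of
    change between two time points -- to apply a condition (a clinical
    intervention, a perturbation) to a multivariate longitudinal trajectory at
    an arbitrary future time in a single generation step, preserving history
    and unaffected variables. Provides a gated-recurrent or self-attention
    sequence encoder, a condition adapter over frozen condition embeddings, a
    concept bottleneck with multiplicative decoding, Huber-loss training with
    optional gradient-reversal treatment balancing, tau-step-ahead
    counterfactual prediction, direct concept intervention, SimpleLinear and
    vector-autoregression baselines, and synthetic-data simulators (a
    multiplicative-dynamics world with known ground-truth concepts and a
    pharmacokinetic-pharmacodynamic tumor-growth benchmark with tunable
    time-varying confounding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
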