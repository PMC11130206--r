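Package: probepref
Title: Bayesian Analysis of Dot-Probe Attention and Two-Alternative
    Preference Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, filtering and Bayesian analysis of two
    behavioural paradigms used in comparative cognition: a dot-probe
    immediate-attention task with reaction-time outcomes and a
    two-alternative preference task with binary choices. Provides seeded
    trial schedulers and generative simulators mirroring both designs,
    median-absolute-deviation outlier filtering of reaction times with
    repetition-session bookkeeping, per-subject robust Student-t
    regression and a Bernoulli logistic mixed model fitted by MCMC
    (JAGS), posterior effect-size indices (median, MAD, highest-density
    intervals, probability of direction), and a Beta-Binomial
    posterior-predictive switch-count test for temporal clustering of
    binary choice series, with an exact enumeration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    coda,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
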