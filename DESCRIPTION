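Package: lccm
Title: Laminar Neural Mass Modeling of Auditory Evoked-Response Habituation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inversion of a laminar local cortical
    circuit model (LCCM) of auditory cortex. Five neural masses with
    layer-specific excitatory and inhibitory connections are coupled through
    alpha-kernel synaptic transforms; every excitatory connection carries an
    activity-dependent synaptic efficacy driven by depletion and recycling of
    the readily releasable vesicle pool, which generates short-term
    habituation of the simulated N100m source waveform. The package provides
    the classical three-population Jansen-Rit circuit as a baseline, a
    deterministic fixed-step RK4 integrator, generation of tone-train
    stimulation paradigms, synthetic source-waveform datasets with known
    ground truth, an Expectation-Maximization Gauss-Newton scheme for
    posterior estimation under re-parameterized Gaussian priors, and Laplace
    log-evidence model comparison via Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
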