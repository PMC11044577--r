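Package: memkernel
Title: Memory Kernel Extraction for Generalized Langevin Dynamics from
    Discretized Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extraction of friction memory kernels of the generalized
    Langevin equation (GLE) from uniformly sampled one-dimensional
    reaction-coordinate trajectories.  Implements two complementary
    schemes: direct inversion of the Volterra equation relating the
    running kernel integral to velocity and potential-gradient
    correlation functions, and Gaussian-process optimization (GPO) of
    GLE parameters by matching discretized two-point correlation
    functions, which remains usable when the sampling interval exceeds
    the memory time.  Includes potential-of-mean-force estimation by
    Boltzmann inversion, FFT correlation estimators, multiexponential
    kernel fitting, GLE simulation via a Markovian embedding with
    overdamped auxiliary variables, mean first-passage-time analysis,
    and a synthetic ground-truth reference generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
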