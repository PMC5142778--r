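Package: popdim
Title: Dimensionality of Shared Variability in Neural Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates balanced excitatory-inhibitory spiking networks with
    and without clustered excitatory connectivity, bins spike trains into
    trial-by-neuron count matrices, and characterizes the shared component
    of spike-count variability with factor analysis fitted by
    expectation-maximization. Latent dimensionality is selected by
    cross-validated likelihood; derived metrics include shared
    dimensionality (the number of eigenmodes of the shared covariance
    needed to capture 95 percent of its trace), percent shared variance per
    neuron and per mode, and principal angles between mode subspaces
    estimated from different neuron counts. Includes subsampling protocols
    for neuron-, trial- and cluster-representation scaling curves and
    seed-deterministic synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
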