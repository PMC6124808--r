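Package: zebradcm
Title: Spectral Dynamic Causal Modelling of Seizure Dynamics in Calcium
    Imaging Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers slow changes in effective brain connectivity from
    regional calcium-imaging time series recorded during acute epileptic
    seizures.  Regional population activity is described by three-population
    neural mass models whose linearised steady-state response yields
    predicted cross-spectral densities; a calcium-indicator kernel maps
    simulated local field potentials to fluorescence.  Windowed
    cross-spectral features are fitted by variational Laplace, competing
    network architectures are scored by Bayesian model reduction with
    family-wise comparison, and slow parameter fluctuations across a seizure
    are modelled by a second-level parametric empirical Bayes model over
    temporal basis functions.  A synthetic-data module generates fully
    ground-truthed surrogate experiments emulating light-sheet recordings of
    PTZ-induced seizures in larval zebrafish, so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
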