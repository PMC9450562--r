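Package: spikedyn
Title: Criticality Diagnostics for Neural Population Spike Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assesses where a neural population's spontaneous activity sits on
    the asynchronous-reverberating-critical spectrum. Provides neuronal
    avalanche extraction and scaling analyses (discrete power-law fitting with
    likelihood-ratio model comparison, size-given-duration exponent, avalanche
    shape collapse and the crackling-noise consistency check), multistep
    regression (MR) estimation of the branching parameter with a
    stationarity/Poisson test battery and timescale conversion, spike-count
    covariance and participation-ratio dimensionality diagnostics, and a
    synthetic-data module (driven branching processes, a 4-neighbour lattice
    network, binomial and systematic subsampling, temporal coarsening and
    time-shuffled surrogates) so every stage is verifiable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
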