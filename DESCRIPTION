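Package: prfmap
Title: Population Receptive Field Mapping and Simulation for Retinotopic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population receptive field (pRF) mapping of visual
    cortex from fMRI time series: sweeping-bar stimulus aperture generation,
    a two-dimensional Gaussian pRF forward model with haemodynamic response
    convolution, two-stage (coarse grid plus derivative-free fine) parameter
    fitting, temporal low-pass filtering, split-half noise-ceiling estimation
    via the Spearman-Brown prophecy formula, neighbour-polygon cortical
    magnification on triangulated surface patches, and eccentricity-binned
    summaries with bootstrap confidence intervals. A synthetic-data generator
    produces multi-run BOLD data with known ground truth so that the full
    pipeline, including the effect of temporal filtering on pRF size
    estimates, can be studied in desk-scale simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
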