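Package: placenet
Title: Normative Place-Cell Networks with Center-of-Mass Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates foraging trajectories in polygonal and circular
    arenas, trains a recurrent neural network to path-integrate while its
    position is read out through a fixed, place-cell-inspired
    center-of-mass decoder, and provides the analysis battery used to
    characterize the learned spatial representations: occupancy-normalized
    ratemaps, spatial and population-vector correlations with shuffled
    nulls, rate overlap and difference, Skaggs spatial information, PCA
    spectra, weight diagnostics, and edge-corrected Ripley K/H statistics
    with kernel density estimates for field-center clustering. Includes
    multi-environment remapping experiments, geometric manipulations of
    familiar arenas, noise injection, context mismatch, and velocity
    ablation protocols with frozen weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
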