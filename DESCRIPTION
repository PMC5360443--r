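Package: hftag
Title: Hierarchical Frequency Tagging: Stimulus Generation, EEG Simulation
    and Spectral Analysis
Version: 0.1.0
Authors@R: person("HFT", "Maintainers", email = "hftag@example.org",
    role = c("aut", "cre"))
Description: Tools for hierarchical frequency tagging experiments combining
    semantic wavelet-induced frequency tagging (SWIFT) with steady-state
    visual evoked potential (SSVEP) contrast modulation. Provides cyclic
    wavelet-domain image scrambling based on an orthonormal discrete Meyer
    transform, assembly of certainty-controlled trial movies, a synthetic
    multichannel EEG forward model with a controllable top-down by bottom-up
    nonlinearity, neighbour-bin signal-to-noise spectral statistics with
    intermodulation bookkeeping, behavioural and EEG quality control, and
    linear mixed-effects analysis of certainty effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
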