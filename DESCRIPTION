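Package: seqReach
Title: Joint Directional Tuning and Population Readout for Reach Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of motor-cortical population activity
    during memory-guided double-reach tasks. Generates trial-structured
    surrogate spiking/rate datasets with known directional tuning (single
    cosine, additive, multiplicative gain-modulated, and full joint models),
    fits and compares joint cosine-tuning models over sliding windows with
    permutation chance levels, embeds preparatory activity with PCA-LDA-QR
    and decodes reach directions, computes population-vector readouts, and
    trains continuous-time recurrent network models that emit desired
    population vectors for 36-condition reach sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
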