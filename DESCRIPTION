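Package: promnet
Title: Neural-Network Prediction and Quantitative Design of Promoter and RBS Strength
Version: 0.1.0
Authors@R:
    person("promnet", "developers", email = "promnet@example.org", role = c("aut", "cre"))
Description: Tools for quantitative design of bacterial regulatory elements
    (promoter plus ribosome binding site) from mutant libraries with measured
    relative expression strengths. Sequences are one-hot encoded and fed to a
    single-hidden-layer backpropagation neural network trained by batch
    gradient descent with momentum and an adaptive learning rate. Includes
    grid-search model selection over training-set size and hidden-layer width,
    in-silico saturation mutagenesis scanning with key-point classification,
    two de-novo design procedures (in-silico library screening and key-point
    combination search), a position-weight-matrix baseline, per-position
    information-content conservation profiles, and a seeded synthetic-library
    generator with a planted sequence-to-strength ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
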