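Package: smtrace
Title: Single-Molecule TIRF Trace Simulation, Idealization and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule total internal reflection
    fluorescence (TIRF) experiments on oligomerizing RNA-binding proteins.
    Simulates photobleaching, oligomer association/dissociation, RNA-release
    and two-colour intensity traces together with rendered camera image
    stacks; detects spots and extracts background-corrected traces; idealizes
    traces into piecewise-constant levels with a Gaussian-emission hidden
    Markov model; calibrates the single-fluorophore intensity unit and
    converts steps to integer molecule counts; fits single-exponential
    dwell-time and ensemble-decay models with right-censoring support; and
    classifies colocalized two-colour pairs into dissociation pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
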