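Package: nrsdm
Title: Nested Repeated Sequence Decomposition of Symbolic Texts and Numeric Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts real-valued series into symbolic texts through parameterized
    discretization scales (linear, tangential, hyperbolic), decomposes texts into a
    tree of nested exact repeated sequences by greedy longest-first search with
    occurrence masking, and characterizes the result with entropy-based complexity
    measures (nested pattern complexity and multiscale integral complexity) and two
    probability-versus-length representations with equal-repetition bands. Includes
    simulators for the logistic map, the Lorenz system, and planted nested-periodic
    texts, plus CSV/FASTA/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    optparse,
    seqinr,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
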