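Package: scenebind
Title: Willshaw Associative Memory and Quantum-Inspired Search for Visual Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the sub-symbolic combination (binding) problem in a
    synthetic blockworld: binary pictograms are encoded into cognitive
    entities (identity bitmap plus abscissa and ordinate bars), stored
    categories are learned by a Willshaw-type binary associative memory
    (Lernmatrix), and candidate object combinations are screened by
    familiarity discrimination (the Hopfield-style quadratic form or the
    cosine between a cue and its one-step retrieval). The familiarity test is
    also realized as a reversible circuit (Toffoli, Peres adder, full
    subtractor) forming a search oracle, and a Grover amplitude-amplification
    simulator over the combination-index space demonstrates the hybrid
    quantum/classical retrieval of stored visual categories from noisy
    scenes, together with the associated gate-count and query-cost analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
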