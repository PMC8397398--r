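Package: polyample
Title: Sequence-Controlled Conformations of Markov Polyampholytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how charge-sequence blockiness controls the
    conformations of statistically neutral polyampholytes. Generates quenched
    first-order Markov charge sequences with tunable correlation, provides
    exact ensemble statistics (block charge, net-charge variance,
    characteristic charge), classifies chains into five conformational
    regimes (globule, pearl-necklace variants, stretched polyelectrolyte)
    from closed-form scaling laws, minimizes a necklace free energy to
    locate the bead-to-string charge-migration boundary, and verifies
    predictions with a coarse-grained Langevin simulator and a
    pearl-detection trajectory analyzer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
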