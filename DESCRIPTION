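Package: hpfold
Title: Hill-Climbing Evolutionary Search for 2D HP Lattice Protein Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein structure prediction in the two-dimensional
    hydrophobic-polar (HP) square-lattice model with an evolutionary
    algorithm built on hill-climbing genetic operators. Conformations are
    encoded as absolute-move chromosomes over L/U/R/D; the mutation
    primitive is the pull-move transformation, applied in steepest-ascent
    and random hill-climbing modes, and recombination is a
    collision-avoiding one-point crossover driven in a hill-climbing loop.
    A periodic diversification stage replaces Hamming-similar
    equal-energy individuals with fresh random conformations. Includes
    the standard 20-64 residue 2D HP benchmark instances with their best
    known energies, four algorithm variants (EA, EAD, EAHC, EAHCD),
    seeded multi-run drivers, and best-to-date run statistics (envelope
    summaries, signed Welch t comparisons, population free energy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
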