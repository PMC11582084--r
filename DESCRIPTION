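Package: karyevo
Title: Phylogenetic Comparative Analysis of Karyotype Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying karyotype evolution on time-calibrated
    phylogenies, motivated by the chromosome complements of leafcutting
    ants (Atta, Acromyrmex, Amoimyrmex) and their relatives. Parses
    karyotype formula strings (Levan nomenclature) into per-morphology
    chromosome counts and derives quantitative traits (haploid number,
    per-class counts, fundamental number); tests phylogenetic signal
    (Moran's I, Abouheif's Cmean, Blomberg's K, Pagel's lambda); fits
    Brownian motion and lambda/delta/kappa/Ornstein-Uhlenbeck tree
    transformations by phylogenetic generalised least squares with
    AICc model selection; detects clade rate shifts by a greedy
    traitMEDUSA-style search; fits ChromEvol-style continuous-time
    Markov models of haploid chromosome number (dysploidy, polyploidy,
    demi-polyploidy, constant or linear rates) with marginal ancestral
    reconstruction; and implements a bidimensional karyograph model of
    joint chromosome-number and arm-number evolution embedded in a
    multi-state speciation-extinction (MuSSE) likelihood, with
    likelihood-ratio comparison of models with and without
    polyploidisation. A seeded synthetic-data module simulates
    birth-death trees, continuous traits, and discrete karyotype
    histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
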