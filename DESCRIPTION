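Package: polusage
Title: Deconvolution of Replicative DNA Polymerase Usage from Ribonucleotide End-Count Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking the division of labor among the replicative DNA
    polymerases (Pol alpha, delta and epsilon) genome-wide from strand-specific
    ribonucleotide-derived end-count tracks. Implements restriction-site
    internal-standard normalization with untreated-control background
    subtraction, algebraic three-strain deconvolution of per-bin per-strand
    polymerase synthesis fractions, the DDAF statistic (deviation from the
    expected Pol delta/alpha fraction of synthesis) with anchor-aligned
    meta-profiles and peak-area quantification, origin calling from abrupt
    strand-concordant shifts in Pol epsilon usage, and a Monte Carlo simulator
    of replication-fork collisions with origin-efficiency estimation and
    fitting of fork velocity, firing-time dispersion and collision tract
    length. A synthetic-data generator produces ground-truth synthesis
    fractions and realistic end-count samples from a simulated replication
    program, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
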