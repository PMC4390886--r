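Package: hipscan
Title: Survey of Highly Iterated Palindromes and a Methylation-Directed
    Mismatch-Repair Ratchet Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide survey tools for highly iterated palindromes (HIPs)
    such as the cyanobacterial octamer GCGATCGC (HIP1): exact and degenerate
    IUPAC oligomer counting with strand-collapsed conventions, expected counts
    under nucleotide-composition and Markov null models, observed/expected
    ratios with a binomial deviation (shade) scale and filtered counts,
    per-genome top-oligomer and palindrome-class surveys, iterative detection
    of conserved palindromic flanking extensions, and per-position one-off
    deviation profiles with optional flanking-context restriction.  Also
    includes a stochastic simulator of a proposed G-meC-directed
    mismatch-repair ratchet that creates and maintains HIP sites, and seeded
    synthetic-genome generators (planted motifs, extension mixtures, deviant
    spectra) so the whole pipeline is testable without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
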