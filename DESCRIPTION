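Package: mazfscan
Title: Endoribonuclease Cleavage-Site Mapping and Motif-Burden Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps sequence-specific endoribonuclease (MazF-family toxin)
    cleavage sites from per-position read-coverage profiles via the relative
    coverage increase (RCI) statistic, builds a nucleotide frequency matrix
    and information-content profile from the aligned cleavage windows, and
    calls the consensus cleavage motif. A per-CDS binomial burden statistic
    (site probability p, expected count E, observed count K, upper-tail
    probability P) ranks coding sequences by predicted cleavage
    susceptibility. Includes a seeded simulator that generates reference
    sequences, cleavage-derived 5'-end coverage profiles, and motif-enriched
    CDS sets with known ground truth, so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
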