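Package: cuparray
Title: Analysis and Simulation of CUP1 Tandem Gene Arrays in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing tandem arrays of the Saccharomyces
    cerevisiae copper-metallothionein gene CUP1: breakpoint and
    microhomology mapping of repeat junctions, repeat-unit period
    inference and type classification, copy-number estimation from
    virtual EcoRI restriction digests and from relative read depth,
    in-silico PCR assays for array presence and repeat size, a
    mechanistic simulator of array genesis by unequal nonhomologous
    end-joining and of array expansion/contraction by unequal crossover,
    pop-out and single-strand annealing, Luria-Delbruck fluctuation
    analysis with the Lea-Coulson method of the median, and a
    deterministic synthetic-locus generator with full truth logging so
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
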