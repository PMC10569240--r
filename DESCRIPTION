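Package: t2tfinish
Title: Finishing Toolkit for Telomere-to-Telomere Plant Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational finishing stages of gap-free
    (telomere-to-telomere) plant genome assemblies: long-read filtering,
    tiered flank-anchored gap filling, telomeric repeat detection and
    chromosome-end patching, centromere delimitation from tandem-repeat and
    gene-density profiles, k-mer based genome-size and assembly quality (QV)
    estimation, structural-variant screening against gene sets with ecotype
    frequencies, and Ks-based divergence dating. Includes a synthetic-genome
    simulator with planted ground truth (telomeres, centromeres, gaps,
    structural variants) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
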