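Package: amplishot
Title: Shotgun 16S rRNA Amplicon Profiling In Silico
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico framework for shotgun sequencing of 16S rRNA
    amplicons. Provides IUPAC-aware degenerate-primer universality scoring
    and in-silico PCR, greedy OTU clustering for comparing end-read versus
    whole-amplicon resolution, a paired-end shotgun read simulator with
    empirical per-cycle error profiles, expectation-maximization
    reconstruction of amplicon sequences with relative-abundance
    estimation, best-hit taxonomic classification with identity thresholds
    per rank, a paired-read same-OTU concordance classifier, and
    precision/recall/correlation evaluation against known mock
    communities. A synthetic 16S-like reference-database generator with
    conserved/variable block architecture stands in for public rRNA
    databases so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
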