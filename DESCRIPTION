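Package: mitokey
Title: PCR-RFLP Species Identification and Mitogenome Quality Control for
    Helicoverpa Pests
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: In-silico PCR-RFLP diagnostics and mitochondrial genome quality
    control for the five major Helicoverpa pest species (H. armigera,
    H. punctigera, H. assulta, H. zea, H. gelotopoeon). Simulates restriction
    digestion of partial COI amplicons with a degenerate-motif scanner,
    encodes the consolidated five-species diagnostic key, classifies unknowns
    from fragment-length patterns and searches for minimal discriminating
    enzyme panels. Screens assembled mitogenomes for misidentification via
    per-gene and whole-molecule nucleotide identity (banded affine alignment
    for full-length molecules), localizes chimeric segments by assigning
    diagnostic SNPs to donor species and segmenting the donor track, and
    sanity-checks species clustering with a neighbor-joining phylogeny over
    Kimura two-parameter distances on concatenated protein-coding genes. A
    seeded synthetic-fixture generator produces amplicons, mitogenome panels
    at target identities, and chimeras with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
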