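Package: barcodeval
Title: Evaluation of DNA Barcode Reference Libraries for Species Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether a DNA barcode reference library can
    discriminate the species it contains, with emphasis on short hypervariable
    mitochondrial 12S amplicons (the MiFish region) nested inside longer 12S
    fragments. Implements pairwise global alignment with affine gaps,
    uncorrected p-distance and Tamura-Nei (TN93) distances under pairwise
    deletion, neighbour-joining trees with nonparametric bootstrap support,
    in-silico excision of amplicon subregions by degenerate primer matching,
    and a deterministic Match/Split/Merge/Mixture classification of species
    with a configurable distance caution threshold. A sequence-evolution
    simulator (TN93 model with a planted hypervariable core, conserved primer
    sites, mitochondrial introgression and shared-haplotype events) generates
    reference libraries with known ground truth so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
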