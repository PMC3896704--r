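Package: kindredscan
Title: Identity-by-Descent Variant Prioritization in Extended Multiplex Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare, potentially damaging variants shared
    identical-by-descent (IBD) by all affected members of extended multiplex
    pedigrees. Implements multipoint all-affected IBD sharing via a
    Lander-Green inheritance-vector hidden Markov model, windowed linkage
    disequilibrium pruning, a sliding-window IBD segment caller, a variant
    filter cascade (call quality, predicted-damaging effect, rarity and
    novelty tiers, segregation under heterozygous, homozygous and X-linked
    inheritance models, IBD restriction), cross-family gene summaries,
    hypergeometric candidate-gene enrichment, cross-platform genotype
    concordance QC, and a gene-dropping simulator that generates pedigrees,
    marker maps, array genotypes and annotated exome variant tables with
    injected causal variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
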