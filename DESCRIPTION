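Package: haplopop
Title: Haplotype Construction for Population Assignment from Phased SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Combines phased SNP markers into multi-allelic haplotype loci
    that maximise the informativeness for assignment (IA) of individuals to
    predefined populations.  A windowed greedy algorithm merges the pair of
    markers with the largest positive gain of informativeness for assignment
    (GIA) until no merge improves the objective, producing a haplotype coding
    that can be applied to recode any phased dataset (the LEARN/APPLY
    two-step procedure).  Recoded data are assigned to populations by
    principal component analysis on a presence/absence haplotype-allele
    encoding with nearest-barycenter classification, evaluated by
    split-validation.  Includes a coalescent simulator of a three-population
    divergence model for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
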