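Package: haplostruct
Title: Mitochondrial Haplotype Structure, Networks and Historical Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of aligned mitochondrial DNA
    sequences: molecular diversity statistics (S, H, h, pi, d), Tamura-Nei
    genetic distances with gamma rate heterogeneity, pairwise Phi-ST and
    hierarchical AMOVA with permutation significance and FDR correction,
    median-joining haplotype networks with inverse-origin site weighting,
    mismatch-distribution inference under the sudden-expansion model with
    Tajima's D and Fu's Fs neutrality tests and expansion-time dating, a
    Dirichlet-multinomial surrogate for Bayesian haplogroup clustering,
    and a structured-coalescent simulator so every stage can be validated
    on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
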