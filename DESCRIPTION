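Package: phyloseed
Title: Phylogenetic Inference of Metastatic Dissemination from
    Multi-Sample Tumour Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the dissemination history of metastatic cancer
    from multi-region variant and allele-specific copy-number data.
    Implements tiered filtering of ultra-deep targeted sequencing calls,
    estimation of cancer cell fractions by a binomial mixture likelihood,
    Dollo-parsimony phylogenies of somatic point mutations with
    branch-and-bound search and copy-number verification of predicted
    reversions, minimum-event phylogenies of allele-specific copy-number
    profiles with whole-genome-duplication-aware rooting, and downstream
    progression metrics (normalized branch lengths, substitution spectra,
    pairwise clonal-frequency configurations and cross-seeding calls).
    Ships a synthetic-data generator that emulates the multi-sample study
    design the pipeline expects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
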