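Package: mitofounder
Title: Founder Analysis and Molecular-Clock Dating for Human Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial DNA founder analysis on whole
    mitogenomes expressed in the rCRS coordinate system: variant profiling
    against the reference with hotspot/indel site masking and heteroplasmy
    calling, haplogroup classification against a PhyloTree-style motif tree,
    greedy maximum-parsimony haplotype trees with an exhaustive Fitch oracle,
    clade dating by the rho statistic with its genealogy-based standard
    error and by clock-constrained maximum likelihood under a partitioned
    TN93(+I)+Gamma model, BIC substitution-model selection, conversion of
    mutational distances to years with an optionally selection-corrected
    clock, cross-method consensus intervals, northern/southern route
    attribution with intrusive-lineage exclusion, and a coalescent simulator
    with known node times for end-to-end estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
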