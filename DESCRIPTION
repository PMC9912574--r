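Package: troutGS
Title: Single-Step Genomic Evaluation and Breeding-Program Simulation for
    Fillet Yield and Body Weight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-trait pedigree and single-step genomic BLUP (ssGBLUP) for a
    fillet-yield / body-weight breeding program: pedigree relationship matrices
    and their sparse inverses, VanRaden genomic relationship matrices with base
    allele frequencies, Henderson's mixed model equations, AI-REML variance
    components with selected-inverse trace computation, three validation
    schemes (mid-parent, adjusted-phenotype forward validation, and the LR
    method), weighted ssGBLUP with nonlinear-A SNP weights, and window-based
    single-step GWAS. Includes a seeded multi-generation breeding-program
    simulator with divergent selection under an inbreeding constraint that
    emulates the full-sib family structure of an aquaculture nucleus program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
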