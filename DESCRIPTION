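Package: kinvar
Title: Relationship Matrices, REML Variance Components, and the
    Sensitivity of Heritability and Breeding Values to Kinship
    Transformations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds pedigree (A), genomic (G, VanRaden method 1) and
    hybrid single-step (H) relationship matrices and their inverses,
    estimates variance components of the single-trait animal model by
    EM-REML, and solves the mixed model equations for breeding values.
    Implements the linear transformation K* = wK + a11' + bI of a
    relationship matrix K (or of its inverse) and quantifies how the
    transformation propagates into the distribution of the elements of
    K^-1, the estimated heritability, and the correlation and
    regression slope of breeding values against a baseline analysis.
    Includes a discrete-generation pedigree simulator with phenotypic
    selection of dams, gene-dropped marker genotypes, and configurable
    masking of parents and phenotypes, so every stage of the pipeline
    is testable on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
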