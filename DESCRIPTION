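Package: senfuse
Title: Fused Self-Expressive Networks for Multi-Modality Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association analysis between single-nucleotide polymorphism
    genotypes and multi-modality brain phenotype networks. Builds node
    (regional gray-matter volume) and edge (weighted clustering coefficient
    of Pearson functional connectivity) features, estimates diagnosis-
    restricted sparse self-expressive subject networks per modality by
    nonnegative sparse coding, fuses them into a single network by an
    iterative class-guided diffusion, and regresses additively coded
    genotypes on the network-reconstructed features with L2,1-norm joint
    feature selection. Includes repeated nested cross-validation, a
    comparison ladder of single-, concatenated- and multi-modality
    variants, genome-wide SNP screening, ROI and edge ranking, and a
    class-subspace synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
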