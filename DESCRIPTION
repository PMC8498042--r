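Package: rrgskit
Title: Simulation and Analysis of Reciprocal Recurrent Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse a two-pool reciprocal recurrent
    genomic selection (RRGS) breeding programme for hybrid wheat. Provides a
    forward-in-time population simulator (founder genomes, round-robin
    crossing, meiosis under the Haldane map function, single-seed descent,
    additive plus dominance trait architectures, multi-environment trials
    with a stress-environment regime, vegetation-index profiles), ridge
    regression BLUP with additive and dominance marker effects, GBLUP with
    the VanRaden genomic relationship matrix, general combining ability
    prediction against tester panels, k-fold and chessboard (T0/T1/T2)
    cross-validation, phenotypic mixed-model analysis (BLUEs, robust
    outlier control, GCA/SCA variance components, heritability, heterosis),
    response-to-selection theory with finite-population selection
    intensities, and genotype-by-environment diagnostics (interaction-effect
    clustering, PCA, Mantel tests, vegetation condition indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
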