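Package: ssgblup
Title: Single-Step Genomic BLUP Evaluation for Multi-Trait Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based and single-step genomic best linear unbiased
    prediction (pedBLUP and ssGBLUP) for multi-trait animal models at desk
    scale. Implements pedigree validation and topological ordering,
    Meuwissen-Luo inbreeding, numerator relationship matrices and their
    sparse inverses via Henderson's rules, VanRaden genomic relationship
    matrices with genotype quality control, the single-step H-inverse with
    tau/omega adjustments, exact multi-trait mixed-model equations with
    trait-specific fixed effects and missing records, EM-REML variance
    component estimation, and the two breeding-value accuracy metrics
    (correlation of EBV with GEBV, and per-animal reliability from
    prediction error variance) stratified by animal information type and
    bull type. A gene-dropping simulator generates pedigrees, genotypes,
    and correlated phenotypes for end-to-end evaluation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
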