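Package: ecgherit
Title: Pedigree-Based Heritability of ECG Traits with SNP Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood polygenic variance-component estimation of the
    narrow-sense heritability of electrocardiographic traits (PR, QRS, QT and
    the Sokolow-Lyon, Cornell and 12-lead-sum voltage-duration products used as
    left-ventricular-hypertrophy proxies) in extended pedigrees. Computes
    kinship matrices and inbreeding coefficients from family structure,
    constructs analysis-ready traits (Bazett heart-rate correction, covariate
    residualization, rank-based inverse-normal transformation, per-trait ECG
    exclusion rules), and quantifies how much of each trait's heritability is
    explained by known genome-wide-significant variants through a three-model
    conditioning procedure with likelihood-ratio tests, including
    cross-phenotype SNP-set decompositions. A gene-dropping simulator generates
    family cohorts with known variance composition for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
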