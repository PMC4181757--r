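Package: episcape
Title: SNP-SNP Interaction Scanning on Additive, Multiplicative and
    Model-Free Scales for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scanning pairs of biallelic markers for statistical
    epistasis in case-control data using three complementary definitions of
    interaction: departure from additivity of excess risks (relative excess
    risk due to interaction and the attributable proportion, with
    delta-method confidence intervals), departure from multiplicativity
    (the product-term coefficient of a saturated logistic model), and
    multifactor dimensionality reduction (high/low risk cell labelling
    scored by balanced accuracy with cross-validation consistency).
    Includes genotype input from PLINK-style text or TSV dosage files,
    dominant/recessive exposure codings with preventive-factor recoding,
    Cochran-Armitage single-marker tests and two-cohort meta-analysis,
    ReliefF-based marker prioritisation, permutation-based family-wise
    error correction, classifier metrics (category-concordance AUC,
    sensitivity/specificity, attributable fraction), LD pruning of top hit
    lists, cross-method correlation, and a case-control genotype simulator
    with configurable two-locus effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
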