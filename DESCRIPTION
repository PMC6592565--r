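Package: prsphewas
Title: Polygenic Risk Score Construction and PheWAS on Coded Phenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds polygenic risk scores (PRS) from external genome-wide
    association sources and screens them against an electronic-health-record
    phenome. Implements harmonization and quality control of association
    catalog entries (strand correction, ambiguous-variant exclusion, risk
    allele frequency checks, linkage-disequilibrium deduplication), greedy LD
    clumping with p-value thresholding, point-normal posterior reweighting of
    genome-wide summary statistics with windowed LD (infinitesimal closed form
    and Gibbs sampler), dosage-based scoring with locus merging and
    shared/unique subtype decomposition, PheCode aggregation of ICD9/ICD10
    diagnosis events with Mahalanobis-matched case-control studies, Firth
    bias-reduced logistic regression for phenome-wide association scans
    (standard, exclusion, and lagged secondary-diagnosis modes), train/test
    evaluation (AUC, Hosmer-Lemeshow, Brier, Nagelkerke), and export of a
    static results catalog. A synthetic-data generator with block-LD
    genotypes, three disease subtypes sharing causal loci, and a dated coded
    phenome makes the whole pipeline testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
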