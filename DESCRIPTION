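Package: haploaip
Title: Haplotype-Based Allelic Identity Prediction and QTL Fine-Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how well haplotype-based allelic identity
    predictors (AIP) recover the unobserved allelic identity at a tested
    locus, and how that prediction quality relates to multiallelic linkage
    disequilibrium (LD) and to QTL mapping accuracy.  Implements six
    predictors (single-marker IBS, haplotype IBS, the Li-Jiang similarity
    score, a coalescent IBD probability, a least-squares trained predictor,
    and an adapter for external haplotype clusterings), the normalized
    entrywise matrix distance between predictor similarity matrices and the
    true identity matrix at a QTL, multiallelic LD measures and LD profiles,
    gene-drop simulation of founder haplotypes through a pedigree with an
    additive hidden QTL, EM-REML variance-component association scans with
    restricted likelihood-ratio tests, and the relative-efficiency and
    mapping-accuracy comparison framework, together with synthetic
    population generators so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
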