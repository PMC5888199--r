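Package: riskQTL
Title: Cell-Type eQTL Mapping at Disease Risk Loci with Permutation-Based
    Family-Wise Error Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping cis- and trans-acting expression quantitative
    trait loci (eQTLs) at predefined disease risk loci in purified immune cell
    populations. Implements post-imputation genotype quality control (call
    rate, minor allele frequency, INFO score, region blacklists), microarray
    expression normalization with linear-model batch correction and principal
    component diagnostics, linkage-disequilibrium block expansion of index
    SNPs (r-squared proxies), window-based cis/trans probe classification,
    per SNP-probe linear-model association with Pearson and Spearman
    statistics, experiment-wide significance thresholds from the minimum-P
    permutation procedure, Benjamini-Hochberg comparison, and covariate
    robustness analysis. Includes a synthetic cohort generator with block LD,
    planted additive cis effects, batch and clinical covariate structure, and
    a ground-truth ledger for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, Genetics, SNP, GeneticVariability, QualityControl,
    Normalization, StatisticalMethod
RoxygenNote: 7.3.3
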