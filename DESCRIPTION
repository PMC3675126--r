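Package: bvlr
Title: Weighted Bayesian Multi-Variant Liability Regression for Causal
    Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects causal variants in case/control sequence data with a
    weighted Bayesian multi-variant liability (probit) regression fitted by
    Gibbs sampling. Per-variant shrinkage priors are informed by linkage
    disequilibrium with genome-wide association signals and by phastCons
    sequence conservation; family-wise significance is assessed by
    phenotype-permutation min-p / max-z tests. Includes the full two-stage
    (GWAS then sequencing) disease simulation used to evaluate power and
    false positive rate: a neutral coalescent haplotype pool, a dominant
    genotypic-relative-risk disease model, and exome-style liability
    phenotype simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
LinkingTo: Rcpp
SystemRequirements: Python (>= 3.8) with msprime, for coalescent pool
    simulation only.
Config/testthat/edition: 3
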