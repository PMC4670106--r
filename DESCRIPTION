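Package: desweep
Title: Differential Expression Scoring and Ranked-Subset Geneset Enrichment
    Sweeps for Brain RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for case/control bulk RNA-seq
    count data, built around post-mortem Huntington's disease (HD) brain
    studies. Provides count preprocessing (low-signal filtering, per-group
    Tukey-fence outlier winsorization, median-of-ratios normalization, a
    closed-form variance-stabilizing transform), negative-binomial Wald
    differential expression with categorical covariate adjustment and FDR
    control, the composite Differential Expression Score (DES = mean
    normalized counts x |log2 fold change| x -log10 adjusted p), a
    hypothesis-free geneset enrichment method that tests nested ranked
    subsets of the DE list (top 25, 50, ...) for hypergeometric
    over-representation and integrates per-collection profiles by row
    normalization and Ward clustering, and per-gene association of
    variance-stabilized expression with clinical covariates (CAG repeat
    length, CAG-adjusted onset, Hadzi-Vonsattel involvement scores).
    A negative-binomial simulator with planted differential expression and
    planted genesets makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
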