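Package: descore
Title: Composite Differential-Expression Scoring for Small-Sample RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for ranking genes in two-group
    RNA-seq designs by a composite differential-expression (DE) score that
    integrates direction of change, statistical confidence and expression
    abundance: sign(log2FC) x (-log10 p) x min-max-scaled average
    expression. Includes TMM and DEGES-iterated count normalization with a
    negative-binomial exact test, resampling-based reproducibility
    validation (stratified bootstrap, leave-one-out subsampling,
    permutation nulls, Jaccard indices), exhaustive-enumeration PERMANOVA,
    ANOSIM and MANOVA for small designs, hypergeometric over-representation
    analysis and preranked GSEA with Wang semantic-similarity clustering of
    ontology terms, hub-gene and pathway prioritization scores, and
    cross-species ortholog concordance analysis. A self-contained
    negative-binomial simulator emulating hemizygous-deletion designs makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    edgeR,
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
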