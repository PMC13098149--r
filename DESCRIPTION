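Package: comodbm
Title: Cross-Species Comorbidity Mapping from Unified Phenotype Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes species-specific phenotype ontology annotations from
    human, mouse, zebrafish, fruit fly and roundworm databases into a unified
    19-category structure (18 whole-body categories plus an additive Fertility
    category with 13 reproductive groups), filters ortholog predictions by
    confidence and dates each gene's conservation, assembles gene x species x
    category phenotype-count profiles against genome backgrounds, and runs the
    downstream statistical suite: per-category Fisher exact enrichment with
    pooled Benjamini-Hochberg FDR control, per-gene cross-species intraclass
    correlation with a permutation null, mouse-human phenotype correlation,
    k-means comorbidity clustering with gap-statistic model selection, and
    multinomial / binary logistic driver models scored by McFadden pseudo-R2
    and likelihood-ratio tests. Includes a fully parameterized synthetic-data
    generator with recorded ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
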