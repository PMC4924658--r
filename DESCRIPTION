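Package: consignet
Title: Consensus Gene Signatures and Network-Based Driver Prioritization
    from Multi-Study Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable in-silico pipeline for deriving robust cancer gene
    signatures and prioritizing candidate driver proteins. Integrates
    multi-study log-scale expression matrices with parametric
    empirical-Bayes batch correction, resamples the integrated cohort into
    virtual case/control datasets scored by a SAM-style permutation
    statistic with FDR control and fold-change filtering, calls consensus
    signatures robust across resamples, expands differentially expressed
    seed proteins into protein-interaction networks reduced by a
    Steiner-tree approximation and ranked by degree and clustering
    coefficient, tests pathway over-representation with the right-tailed
    Fisher exact test, filters paired proteomics by a paired t-test, and
    stratifies survival by median expression split with Kaplan-Meier and
    log-rank comparison. Ships synthetic-data generators emulating every
    input so the whole pipeline is testable without downloads.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
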