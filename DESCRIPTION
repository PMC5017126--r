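Package: stemprint
Title: Gene-Set Enrichment and Single-Sample Ternary Pathway Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class gene set enrichment analysis (weighted Kolmogorov-Smirnov
    running-sum statistic, gene-set permutation null, normalized enrichment
    scores, GSEA-style false discovery rates and leading-edge contribution
    categories) together with a single-sample pathway fingerprint procedure:
    per-sample rank transformation, a one-sided KS pathway activity score,
    a gene-name-permutation null mapped onto the N(0,1) scale through its
    empirical distribution function, ternary (-1/0/+1) standardization at the
    15 percent tails of a reference corpus, and a stemness-distance spectrum
    that places samples on an embryonic-stem-to-differentiated axis. Includes
    a seeded synthetic-data generator (planted differential pathways,
    stemness-gradient corpora) and readers and writers for the GMT, GCT and
    CLS community formats.
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
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
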