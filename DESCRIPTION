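Package: heterodist
Title: Marker-Based Heterosis Prediction in Half-Diallel Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for half-diallel heterosis studies that pair microsatellite
    (SSR) diversity with replicated field trials. Computes per-locus allele
    counts, Nei gene diversity and Botstein polymorphic information content;
    pairwise Nei DA genetic distances among inbred parents with UPGMA
    clustering and Newick export; mid-parent and better-parent heterosis with
    least-significant-difference tests derived from a randomized complete
    block ANOVA; and Pearson correlations between parental genetic distance
    and heterosis. A simulator generates half-diallel datasets with known
    additive and dominance architecture so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
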