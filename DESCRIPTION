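Package: amosaclust
Title: Simultaneous Feature Selection and Semi-Supervised Clustering by
    Archived Multiobjective Simulated Annealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised clustering with wrapper feature selection for
    numeric tabular data, built on archived multiobjective simulated
    annealing (AMOSA). Candidate solutions encode a binary feature mask
    together with a variable number of cluster centres; points are assigned
    by a point-symmetry distance gated by a nearest-neighbour threshold, and
    up to four objectives (Sym-index, Xie-Beni index, adjusted Rand index on
    a small labelled subset, and the number of active features) are optimised
    simultaneously. Includes ablation variants (Euclidean assignment,
    unsupervised feature selection, fixed-feature clustering), a K-means
    baseline, a synthetic-data generator with planted symmetric clusters,
    and the dense-rank / Friedman / Nemenyi protocol for comparing
    algorithms across datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
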