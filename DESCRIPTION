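Package: dotgrn
Title: Differential Gene Regulatory Network Inference via Double Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers differential gene regulatory networks between two
    conditions (e.g. normal versus tumor) from gene expression matrices by a
    two-level optimal transport (OT) scheme. Unpaired samples are first aligned
    by entropic partial OT on a cosine cost in joint principal-component space;
    regulatory links are then scored by the transport plan of a robust
    (unbalanced) OT problem on a Spearman-correlation gene-gene cost, solved by
    the unbalanced Sinkhorn-Knopp iteration. Includes exact linear-programming
    oracles for small instances, a synthetic two-condition expression generator
    with a planted directed network, ranking metrics (AUROC, AUPR, early
    precision), trivial baselines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    rlang,
    readr,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
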