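Package: sigconnect
Title: Gene Expression Signature Searching with Functional Enrichment and
    Drug-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated environment for gene expression signature
    searching (GESS) against HDF5-backed perturbation databases, functional
    enrichment analysis (FEA) of the resulting drug rankings, and drug-target
    network construction. Implements five signature-search algorithms (CMAP
    Kolmogorov-Smirnov connectivity scores, LINCS weighted connectivity
    scores with NCS/tau standardization, gCMAP, Fisher's exact test and
    Spearman/Pearson correlation), duplication-aware target-set enrichment
    (dup_hyperG, mGSEA, mabs), drug-set enrichment, bipartite drug-target
    network export, and a ROC/pAUC benchmarking framework with bootstrap
    significance tests for comparing search methods. A synthetic-data module
    generates planted-cluster signature databases, drug-target annotations
    and category collections so the full workflow can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    grDevices,
    rhdf5,
    igraph,
    jsonlite,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
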