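Package: rdnetwalk
Title: Path-Based Random Walk Prioritization of Disease-Related miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds a heterogeneous miRNA-disease network (RDnet) from a
    miRNA functional-similarity matrix, a disease phenotype-similarity
    matrix, and a table of known miRNA-disease associations, and ranks
    candidate miRNAs for a query disease by the steady state of a random
    walk with restart started from the disease's known miRNAs. Includes
    the five-fold cross-validation ROC/AUC evaluation protocol, a
    synthetic network generator with planted module structure for
    offline benchmarking, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
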