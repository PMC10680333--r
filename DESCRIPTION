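Package: flowrec
Title: Next-Tool Recommendation for Scientific Workflows with a
    Transformer Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines directed-acyclic scientific workflows (Galaxy
    workflow exports or tool-to-tool edge lists) into linear tool
    sequences, builds multi-label (prefix, next-tools) datasets with
    frequency-balanced batch sampling, trains a transformer-encoder
    multi-label classifier (with GRU, CNN and dense comparators) on
    binary cross-entropy, and serves ranked, post-processed next-tool
    recommendations with attention-based interpretability. Includes a
    synthetic workflow-corpus generator with known ground truth, a
    precision-at-k evaluation suite with an infrequent-tool breakdown,
    and single-file model bundles. The neural-network engine (reverse-
    mode automatic differentiation, multi-head self-attention, GRU,
    2-D convolution, Adam) is implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
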