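Package: rnaevi
Title: Automated Exploration, Visualisation and Interpretation of Bulk RNA-seq Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automates the downstream exploration, visualisation and
    interpretation (EVI) stage of bulk RNA-seq analysis. From a sample sheet,
    a normalized expression matrix, differential expression tables and
    annotation databases it builds a master gene table, runs
    over-representation, upstream-regulator, chromosome-level (spatial),
    gene-list overlap and differential-expression-signature analyses, and
    emits a registry of plots across three workflows (normalized expression,
    differential expression and multiple differential expression) together
    with per-plot data files, re-runnable R scripts composed from a snippet
    bin, and a self-contained HTML report. A synthetic-data generator with
    planted ground truth supports end-to-end testing without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2,
    withr
Config/testthat/edition: 3
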