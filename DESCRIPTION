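Package: consite
Title: Constitutive Protein Binding Sites from Multi-Cell-Line ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates protein-DNA binding sites, and flags those bound
    constitutively across cell lines, from the centers of ChIP-seq peaks
    pooled over many datasets. Peak centers on each chromosome are
    recursively partitioned by a binary range tree with a cell-line-coverage
    stopping rule; a Gaussian kernel density estimate is fitted within each
    terminal node; and all local maxima of the density (found by mean-shift
    hill-climbing with Newton polishing) are reported as binding-site
    summits with their modal regions. A site is declared constitutive when
    its modal region holds peaks from replicate datasets in more than a
    cutoff fraction of the available cell lines. Includes a fixed-width
    genomic binning baseline, a synthetic multi-cell-line peak simulator
    with planted ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
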