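Package: annotlink
Title: Compare, Link and Harmonize Cell-Level Annotations Across Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless toolkit for comparing categorical cell annotations
    (cell type assignments, anatomic structures, QC bins) across single-cell
    and Patch-seq studies. Loads cell tables and annotation-metadata tables
    from csv, gzipped csv, feather and h5ad (cell metadata only); filters
    cells by categorical membership or numeric range; computes confusion
    matrices with count, row/column-fraction and Jaccard views, river
    (alluvial) link models, single-value breakdowns with
    disease-direction tags, and direction-concordance tallies;
    probabilistically harmonizes cell type labels across studies via
    conditional proportion tables with a reserved "noMappedCells" label;
    caps table size by even per-cluster subsampling; and renders river,
    confusion, bee swarm and scatter plots to image files with
    unit-testable plot-data sidecars. A single command-line entry point
    exposes every operation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
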