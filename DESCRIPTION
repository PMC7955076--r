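Package: msntx
Title: Morphometric Similarity Networks and Imaging Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of morphometric similarity
    networks (MSNs) and their transcriptomic correlates. Builds per-subject
    MSNs from regional multi-feature tables, derives covariate-adjusted
    case-control t-maps with FDR control, relates regional maps to a
    region-by-gene expression matrix via first-component partial least
    squares with spatial permutation (spin) inference and bootstrap gene
    Z-scores, preprocesses multi-donor microarray bundles in the Allen
    Human Brain Atlas file dialect into a region-by-gene matrix, and runs
    permutation-based gene-list statistics (differential-expression
    correlations, cell-type overlap tests, list-overlap odds ratios).
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
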