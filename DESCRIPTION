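Package: evmir
Title: Extracellular-Vesicle miRNA Biomarker Panel Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering microRNA biomarker
    panels in small extracellular vesicles (EVs) from small RNA sequencing.
    Provides isomiR-tolerant read quantification against a mature-miRNA
    reference, trimmed-mean-of-M-values (TMM) library normalization with
    PCA-based sample quality control, a seven-model attribute-weighting
    ensemble (information gain, gain ratio, chi-squared, Gini index,
    symmetric uncertainty, ReliefF, one-rule) for feature selection,
    ANOVA-based differential expression with signed fold-change conventions,
    cross-compartment panel intersection, and first-principles miRNA
    seed-site scanning of 3'UTR sequences. A negative-binomial synthetic
    data generator with planted effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
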