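Package: omicdriver
Title: Multi-Omics Evidence Integration for Cancer Driver-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate cancer driver genes in a configurable gene
    panel by integrating five evidence channels per cancer type: recurrent
    focal somatic copy-number alteration (a simplified G-score with
    permutation q-values, or ingestion of externally computed GISTIC-style
    tables), mutation-caller consensus (the m-index), recurrent gene fusions,
    paired tumour/normal differential expression by the Wilcoxon signed-rank
    test, and univariate proportional-hazards overall-survival association.
    The five binary conditions are summed into a cancer-specific CS-score
    (0-5) per gene and cancer type, and CS-scores are summed across cancer
    types into a pan-cancer overall PCO-score with a per-channel
    decomposition. Includes a multi-omic cohort simulator with planted
    drivers for end-to-end validation, tidy readers and writers for the
    standard tabular formats (SEG, MAF-lite, BED, TSV matrices), broom-style
    tidiers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
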