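Package: qtgrank
Title: Prioritize Causal Genes in QTL Intervals by Negative-Resampling Random-Forest Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks candidate genes inside linkage-mapping QTL intervals by
    their probability of being the causal gene. Trains random-forest
    classifiers on curated causal genes against negatives resampled from the
    rest of the genome, aggregates thousands of resampled models into a
    prediction-frequency ranking with rank percentiles, and provides the
    supporting machinery: an extended cross-validation framework with
    iterative positive re-splitting and negative resampling, leave-one-out
    delta-AUC feature importance, enrichment ratios, recall-at-cutoff and a
    binomial recall model for multiple QTL, feature engineering from
    effect-annotated variants, co-function network edges and functional
    category maps, and a fully synthetic fixture generator with planted
    causal-gene signal for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
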