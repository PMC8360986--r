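Package: ffpeconcord
Title: Concordance Analysis of Matched Fresh-Frozen and FFPE RNA-Seq Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking exome capture-based RNA-seq of
    formalin-fixed paraffin-embedded (FFPE) tumour samples against TruSeq
    RNA-seq of matched fresh-frozen (FF) tissue. Implements
    cohort-referenced expression-outlier calling (Tukey fence, z-score and
    FPKM floor), global and immune-panel Spearman concordance between
    platforms, molecular-subtype agreement via Cohen's kappa with
    Landis-Koch interpretation, gene-fusion evidence filtering and
    cross-platform detection matrices, RNA-quality (DV200/RIN/block-age)
    correlation analyses, and a synthetic-data generator that emulates a
    paired multi-platform FF/FFPE study with known truth so every stage is
    testable without access-controlled patient data.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
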